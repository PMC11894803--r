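#' Training options for the denoiser
#'
#' @param batch_size minibatch size (default 32).
#' @param learning_rate Adam step size (default 1e-4).
#' @param n_iterations number of optimizer steps.
#' @param ema_decay exponential-moving-average decay for the sampling
#'   weights, in (0, 1) (default 0.999).
#' @param seed integer RNG seed; identical options + data give an identical
#'   loss trace.
#' @param log_interval iterations between progress messages (0 = silent).
#' @return object of class `train_options`.
#' @export
train_options <- function(batch_size = 32L, learning_rate = 1e-4,
                          n_iterations = 2000L, ema_decay = 0.999,
                          seed = 1L, log_interval = 0L) {
  o <- structure(list(batch_size = as.integer(batch_size),
                      learning_rate = as.numeric(learning_rate),
                      n_iterations = as.integer(n_iterations),
                      ema_decay = as.numeric(ema_decay),
                      seed = as.integer(seed),
                      log_interval = as.integer(log_interval)),
                 class = "train_options")
  if (o$batch_size < 1 || o$learning_rate <= 0 || o$n_iterations < 1)
    stop("batch_size, learning_rate and n_iterations must be positive")
  if (o$ema_decay <= 0 || o$ema_decay >= 1) stop("ema_decay must be in (0, 1)")
  o
}

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (k in names(params)) {
    g <- grads[[k]]
    opt$m[[k]] <- beta1 * opt$m[[k]] + (1 - beta1) * g
    opt$v[[k]] <- beta2 * opt$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] -
      lr * (opt$m[[k]] / c1) / (sqrt(opt$v[[k]] / c2) + eps)
  }
  list(params = params, opt = opt)
}

#' Train a denoiser on a normalized, labeled GEM
#'
#' Minimizes the noise-prediction mean squared error over uniformly sampled
#' timesteps and Gaussian noise, conditioning on each sample's phenotype
#' label. An exponential moving average of the weights is maintained and
#' used for all sampling.
#'
#' @param model a `denoiser` from [init_denoiser()].
#' @param gem_train a labeled [gem] with values in \[-1, 1\] and exactly two
#'   label values.
#' @param schedule a `noise_schedule`.
#' @param opts a [train_options()].
#' @return the trained `denoiser`; `$loss_trace` holds the per-iteration
#'   loss and `$label_levels` the condition vocabulary (sorted label
#'   values, condition index = position).
#' @export
train_denoiser <- function(model, gem_train, schedule, opts = train_options()) {
  stopifnot(inherits(model, "denoiser"), is.gem(gem_train),
            inherits(schedule, "noise_schedule"))
  if (is.null(gem_train$labels)) stop("training data must be labeled")
  levels <- sort(unique(gem_train$labels))
  if (length(levels) != model$config$n_conditions)
    stop(sprintf("found %d label value(s), model expects %d",
                 length(levels), model$config$n_conditions))
  x_all <- gem_train$values
  if (ncol(x_all) != model$n_genes)
    stop(sprintf("model built for %d genes, data has %d",
                 model$n_genes, ncol(x_all)))
  if (max(abs(x_all)) > 1 + 1e-9)
    stop("training data must be normalized to [-1, 1]")
  cond_all <- match(gem_train$labels, levels)
  n <- nrow(x_all)
  B <- min(opts$batch_size, n)
  cfg <- model$config
  params <- model$params
  ema <- model$ema
  opt <- if (is.null(model$opt)) .adam_init(params) else model$opt
  trace <- numeric(opts$n_iterations)
  withr::with_seed(opts$seed, {
    for (it in seq_len(opts$n_iterations)) {
      rows <- sample.int(n, B, replace = n < B)
      x0 <- x_all[rows, , drop = FALSE]
      cond <- cond_all[rows]
      t <- sample.int(schedule$T, B, replace = TRUE)
      eps <- matrix(stats::rnorm(B * model$n_genes), B, model$n_genes)
      x_t <- q_sample(x0, t, eps, schedule)
      fw <- .dn_forward(params, cfg, x_t, t, cond, keep_cache = TRUE)
      resid <- fw$eps_hat - eps
      loss <- mean(resid^2)
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at iteration %d; reduce the learning rate", it))
      trace[it] <- loss
      d_eps <- 2 * resid / length(resid)
      grads <- .dn_backward(params, cfg, fw$cache, cond, d_eps)
      st <- .adam_step(params, grads, opt, opts$learning_rate)
      params <- st$params; opt <- st$opt
      d <- opts$ema_decay
      for (k in names(params)) ema[[k]] <- d * ema[[k]] + (1 - d) * params[[k]]
      if (opts$log_interval > 0 && it %% opts$log_interval == 0)
        message(sprintf("iter %d / %d  loss %.5f", it, opts$n_iterations, loss))
    }
  })
  model$params <- params
  model$ema <- ema
  model$opt <- opt
  model$n_iter <- model$n_iter + opts$n_iterations
  model$loss_trace <- c(model$loss_trace, trace)
  model$label_levels <- levels
  model
}

.CKPT_VERSION <- "phenobridge-checkpoint-1"

#' Save / load a model checkpoint
#'
#' A checkpoint bundles everything needed to reproduce sampling in another
#' process: weights (raw + EMA), architecture config, noise schedule, the
#' fitted scaler, gene ids and the label vocabulary.
#'
#' @param model a trained `denoiser`.
#' @param schedule the `noise_schedule` used in training.
#' @param scaler the `scaler_params` fitted on the training split.
#' @param gene_ids character vector of gene ids (training column order).
#' @param path file path.
#' @return `load_checkpoint` returns a list with elements `model`,
#'   `schedule`, `scaler`, `gene_ids`, `label_levels`.
#' @export
save_checkpoint <- function(model, schedule, scaler, gene_ids, path) {
  stopifnot(inherits(model, "denoiser"), inherits(schedule, "noise_schedule"),
            inherits(scaler, "scaler_params"))
  if (length(gene_ids) != model$n_genes)
    stop("gene_ids length does not match the model")
  obj <- list(version = .CKPT_VERSION, model = model, schedule = schedule,
              scaler = scaler, gene_ids = as.character(gene_ids),
              label_levels = model$label_levels)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  force(path)   # argument errors must surface before the read is attempted
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("unreadable checkpoint '", path,
                                           "': ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$version, .CKPT_VERSION))
    stop("checkpoint version mismatch in '", path, "'")
  obj
}
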