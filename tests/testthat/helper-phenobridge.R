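# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; trained models are cached per session
# because several properties are checked against the same toy model.

# --- toy-model study conditions -------------------------------------------
# 16 genes (4 planted), 200 samples per class, T = 100, 2000 iterations:
# small enough to train on one CPU in ~2 minutes, large enough that the
# planted structure dominates the noise.

toy_spec <- function(seed = 11L, n_genes = 16L, n_signal = 4L)
  synthetic_spec(n_per_class = 200L, n_genes = n_genes, n_signal = n_signal,
                 effect_size = 3, noise_sd = 1, seed = seed)

toy_denoiser_config <- function()
  denoiser_config(embed_dim = 64L, n_blocks = 2L, n_heads = 4L,
                  feedforward_dim = 128L)

toy_train_options <- function(seed = 11L, n_iterations = 2000L)
  train_options(batch_size = 32L, learning_rate = 1e-3,
                n_iterations = n_iterations, ema_decay = 0.995, seed = seed)

# Train (once per session per key) a model on a toy two-state GEM and
# return data + splits + checkpoint pieces.
.toy_cache <- new.env(parent = emptyenv())

trained_toy <- function(seed = 11L, n_genes = 16L, n_signal = 4L,
                        n_iterations = 2000L) {
  key <- sprintf("s%d_g%d_k%d_i%d", seed, n_genes, n_signal, n_iterations)
  if (!is.null(.toy_cache[[key]])) return(.toy_cache[[key]])
  sim <- generate_two_state_gem(toy_spec(seed, n_genes, n_signal))
  pp <- preprocess_gem(sim$gem, 0.67, seed = seed)
  schedule <- make_schedule(100L)
  model <- init_denoiser(toy_denoiser_config(), n_genes, seed = seed)
  model <- train_denoiser(model, pp$train, schedule,
                          toy_train_options(seed, n_iterations))
  out <- list(sim = sim, pp = pp, schedule = schedule, model = model,
              checkpoint = list(model = model, schedule = schedule,
                                scaler = pp$scaler,
                                gene_ids = colnames(pp$train$values),
                                label_levels = model$label_levels))
  .toy_cache[[key]] <- out
  out
}

# A very small trained model for interface-level tests (seconds, not
# minutes); quality is irrelevant, only shapes and determinism.
tiny_trained <- function(seed = 3L) {
  key <- sprintf("tiny%d", seed)
  if (!is.null(.toy_cache[[key]])) return(.toy_cache[[key]])
  sim <- generate_two_state_gem(synthetic_spec(40L, 8L, 2L, 3, seed = seed))
  pp <- preprocess_gem(sim$gem, 0.67, seed = seed)
  schedule <- make_schedule(50L)
  cfg <- denoiser_config(embed_dim = 32L, n_blocks = 1L, n_heads = 2L,
                         feedforward_dim = 64L)
  model <- init_denoiser(cfg, 8L, seed = seed)
  model <- train_denoiser(model, pp$train, schedule,
                          train_options(16L, 1e-3, 300L, ema_decay = 0.99,
                                        seed = seed))
  out <- list(sim = sim, pp = pp, schedule = schedule, model = model,
              checkpoint = list(model = model, schedule = schedule,
                                scaler = pp$scaler,
                                gene_ids = colnames(pp$train$values),
                                label_levels = model$label_levels))
  .toy_cache[[key]] <- out
  out
}

# --- independent oracles ---------------------------------------------------

# Brute-force silhouette: plain double loop, no shared code with
# silhouette_score().
brute_silhouette <- function(coords, labels) {
  coords <- as.matrix(coords)
  labels <- as.character(labels)
  n <- nrow(coords)
  euclid <- function(i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- setdiff(which(labels == labels[i]), i)
    if (!length(same)) { s[i] <- 0; next }
    a <- mean(vapply(same, function(j) euclid(i, j), 1.0))
    b <- Inf
    for (lab in setdiff(unique(labels), labels[i])) {
      members <- which(labels == lab)
      b <- min(b, mean(vapply(members, function(j) euclid(i, j), 1.0)))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Brute-force biased MMD with explicit double loops.
brute_mmd <- function(X, Y, sigma) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  k <- function(u, v) exp(-sum((u - v)^2) / (2 * sigma^2))
  acc <- function(A, B) {
    tot <- 0
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
      tot <- tot + k(A[i, ], B[j, ])
    tot / (nrow(A) * nrow(B))
  }
  acc(X, X) + acc(Y, Y) - 2 * acc(X, Y)
}

# schedule stub with chosen alpha_bar values, for closed-form checks
manual_schedule <- function(alpha_bar, beta = NULL) {
  ab <- as.numeric(alpha_bar)
  if (is.null(beta)) beta <- 1 - ab / c(1, ab[-length(ab)])
  structure(list(T = length(ab), kind = "manual", beta = beta,
                 alpha_bar = ab),
            class = "noise_schedule")
}
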