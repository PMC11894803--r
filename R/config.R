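#' Read a pipeline run configuration
#'
#' The configuration is a single YAML file; any value can be overridden
#' programmatically (or from the command line) through `overrides`.
#' Unspecified fields fall back to the workflow defaults: 67% training
#' fraction, gene subsets of 16, UMAP `n_neighbors = 90` / `min_dist =
#' 0.3`, selection at 1 sd, core-gene calling at 2 sd, a 1000-step linear
#' noise schedule.
#'
#' @param path optional YAML file path.
#' @param overrides named list merged over the file values (nested lists
#'   merge recursively).
#' @return a nested list of class `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    paths = list(gem = NULL, labels = NULL, gmt = NULL, outdir = "phenobridge_out"),
    seed = 1L,
    simulate = list(n_per_class = 200L, n_genes = 16L, n_signal = 4L,
                    effect_size = 3, noise_sd = 1),
    preprocess = list(train_fraction = 0.67),
    screen = list(subset_size = 16L, n_neighbors = 90L, min_dist = 0.3,
                  k_sd = 1, background_reps = 0L),
    diffusion = list(T = 1000L, kind = "linear_beta", beta_min = 1e-4,
                     beta_max = 0.02, n_ode_steps = 100L),
    denoiser = list(embed_dim = 128L, n_blocks = 4L, n_heads = 4L),
    train = list(batch_size = 32L, learning_rate = 1e-4,
                 n_iterations = 2000L, ema_decay = 0.999),
    tasks = list(k_sd_core = 2, n_augment = 100L,
                 source_label = "tumor", target_label = "normal"))
  merge_rec <- function(base, new) {
    for (k in names(new)) {
      base[[k]] <- if (is.list(new[[k]]) && is.list(base[[k]]))
        merge_rec(base[[k]], new[[k]]) else new[[k]]
    }
    base
  }
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_rec(cfg, yaml::read_yaml(path))
  }
  cfg <- merge_rec(cfg, overrides)
  if (cfg$preprocess$train_fraction <= 0 || cfg$preprocess$train_fraction >= 1)
    stop("preprocess$train_fraction must be in (0, 1)")
  structure(cfg, class = "run_config")
}

.cfg_path <- function(cfg, name) file.path(cfg$paths$outdir, name)

.write_manifest <- function(cfg, stage, extra = list()) {
  manifest <- c(list(stage = stage, config = unclass(cfg),
                     r_version = as.character(getRversion()),
                     package_version = as.character(
                       utils::packageVersion("phenobridge")),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                extra)
  jsonlite::write_json(manifest, .cfg_path(cfg, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", force = TRUE)
}

.need_file <- function(path, hint) {
  if (is.null(path) || !file.exists(path))
    stop("missing required artifact '", path %||% "<unset>", "'; ", hint)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# falls back to the simulate stage's outputs in outdir when paths are unset
.load_input_gem <- function(cfg) {
  gp <- cfg$paths$gem %||% .cfg_path(cfg, "gem.tsv")
  lp <- cfg$paths$labels %||% .cfg_path(cfg, "labels.tsv")
  g <- read_gem(.need_file(gp, "run the 'simulate' stage or point paths$gem at a GEM TSV"))
  attach_labels(g, .need_file(lp, "point paths$labels at a sample_id<TAB>label table"))
}

#' Run one pipeline stage
#'
#' Orchestrates the workflow end to end, writing every stage's artifacts
#' and a manifest (config echo, seeds, versions, timestamp) under
#' `paths$outdir`:
#' \describe{
#'   \item{simulate}{generate a two-phenotype GEM with planted signal genes
#'     (`gem.tsv`, `labels.tsv`, `signal_genes.txt`).}
#'   \item{screen}{preprocess, partition the genes (or each set of the GMT
#'     in `paths$gmt`) into subsets, score silhouettes, flag extremes
#'     (`screen_report.tsv`).}
#'   \item{train}{preprocess and train the denoiser; writes
#'     `checkpoint.rds` and `loss_trace.tsv`.}
#'   \item{augment}{sample synthetic data from the checkpoint
#'     (`augmented_gem.tsv`, `augmented_labels.tsv`).}
#'   \item{perturb}{bridge source-state samples to the target state;
#'     writes paired matrices and per-gene scores.}
#'   \item{core-genes}{pool perturbation scores and call core genes
#'     (`core_genes.tsv`).}
#'   \item{evaluate}{MMD + SVM report comparing synthetic against held-out
#'     data (`eval_report.tsv`).}
#' }
#'
#' @param stage one of `"simulate"`, `"screen"`, `"train"`, `"augment"`,
#'   `"perturb"`, `"core-genes"`, `"evaluate"`.
#' @param cfg a [read_run_config()] object.
#' @return invisibly, a list of the stage's main in-memory results.
#' @export
run_stage <- function(stage = c("simulate", "screen", "train", "augment",
                                "perturb", "core-genes", "evaluate"),
                      cfg = read_run_config()) {
  stage <- match.arg(stage)
  dir.create(cfg$paths$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- switch(
    stage,
    "simulate" = {
      sim <- generate_two_state_gem(synthetic_spec(
        n_per_class = cfg$simulate$n_per_class, n_genes = cfg$simulate$n_genes,
        n_signal = cfg$simulate$n_signal, effect_size = cfg$simulate$effect_size,
        noise_sd = cfg$simulate$noise_sd, seed = cfg$seed))
      write_gem(sim$gem, .cfg_path(cfg, "gem.tsv"))
      write_labels(sim$gem, .cfg_path(cfg, "labels.tsv"))
      writeLines(sim$signal_genes, .cfg_path(cfg, "signal_genes.txt"))
      sim
    },
    "screen" = {
      g <- .load_input_gem(cfg)
      pp <- preprocess_gem(g, cfg$preprocess$train_fraction, cfg$seed)
      full <- apply_scaler(log2p1(g), pp$scaler)
      subsets <- if (!is.null(cfg$paths$gmt)) {
        sets <- read_gmt(.need_file(cfg$paths$gmt, "provide a GMT file"))
        unlist(lapply(names(sets), function(nm) {
          present <- intersect(sets[[nm]], colnames(full$values))
          partition_gene_set(present, cfg$screen$subset_size, cfg$seed, nm)
        }), recursive = FALSE)
      } else {
        partition_gene_set(colnames(full$values), cfg$screen$subset_size,
                           cfg$seed)
      }
      if (!length(subsets)) stop("no complete gene subsets to screen")
      res <- screen_subsets(full, subsets, cfg$screen$n_neighbors,
                            cfg$screen$min_dist, cfg$seed)
      if (nrow(res) >= 2) res <- select_extremes(res, cfg$screen$k_sd)
      if (cfg$screen$background_reps >= 2) {
        bg <- random_background(full, cfg$screen$subset_size,
                                cfg$screen$background_reps, cfg$seed,
                                n_neighbors = cfg$screen$n_neighbors,
                                min_dist = cfg$screen$min_dist)
        attr(res, "background_mean") <- bg$mean
        attr(res, "background_sd") <- bg$sd
      }
      write_screen_report(res, .cfg_path(cfg, "screen_report.tsv"))
      list(screen = res)
    },
    "train" = {
      g <- .load_input_gem(cfg)
      pp <- preprocess_gem(g, cfg$preprocess$train_fraction, cfg$seed)
      schedule <- make_schedule(cfg$diffusion$T, cfg$diffusion$kind,
                                cfg$diffusion$beta_min, cfg$diffusion$beta_max)
      model <- init_denoiser(denoiser_config(
        embed_dim = cfg$denoiser$embed_dim, n_blocks = cfg$denoiser$n_blocks,
        n_heads = cfg$denoiser$n_heads), ncol(pp$train$values), cfg$seed)
      model <- train_denoiser(model, pp$train, schedule, train_options(
        batch_size = cfg$train$batch_size,
        learning_rate = cfg$train$learning_rate,
        n_iterations = cfg$train$n_iterations,
        ema_decay = cfg$train$ema_decay, seed = cfg$seed))
      save_checkpoint(model, schedule, pp$scaler, colnames(pp$train$values),
                      .cfg_path(cfg, "checkpoint.rds"))
      write_scaler(pp$scaler, .cfg_path(cfg, "scaler.tsv"))
      utils::write.table(
        data.frame(iteration = seq_along(model$loss_trace),
                   loss = model$loss_trace),
        .cfg_path(cfg, "loss_trace.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      list(model = model, schedule = schedule, scaler = pp$scaler)
    },
    "augment" = {
      ck <- load_checkpoint(.need_file(.cfg_path(cfg, "checkpoint.rds"),
                                       "run the 'train' stage first"))
      n <- stats::setNames(rep(cfg$tasks$n_augment, length(ck$label_levels)),
                           ck$label_levels)
      syn <- augment(ck, n, seed = cfg$seed)
      write_gem(syn, .cfg_path(cfg, "augmented_gem.tsv"))
      write_labels(syn, .cfg_path(cfg, "augmented_labels.tsv"))
      list(augmented = syn)
    },
    "perturb" = {
      ck <- load_checkpoint(.need_file(.cfg_path(cfg, "checkpoint.rds"),
                                       "run the 'train' stage first"))
      g <- .load_input_gem(cfg)
      res <- perturb(ck, g, cfg$tasks$source_label, cfg$tasks$target_label,
                     cfg$diffusion$n_ode_steps)
      write_perturbation(res, cfg$paths$outdir)
      list(perturbation = res)
    },
    "core-genes" = {
      score_path <- .need_file(.cfg_path(cfg, "genes_scores.tsv"),
                               "run the 'perturb' stage first")
      tab <- utils::read.table(score_path, header = TRUE, sep = "\t",
                               colClasses = c("character", "numeric", "numeric"))
      fake <- structure(list(per_gene_score = stats::setNames(tab$score, tab$gene),
                             subset_name = "genes"),
                        class = "perturbation_result")
      core <- pool_scores(list(fake), cfg$tasks$k_sd_core)
      utils::write.table(as.data.frame(core), .cfg_path(cfg, "core_genes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(core = core)
    },
    "evaluate" = {
      ck <- load_checkpoint(.need_file(.cfg_path(cfg, "checkpoint.rds"),
                                       "run the 'train' stage first"))
      g <- .load_input_gem(cfg)
      pp <- preprocess_gem(g, cfg$preprocess$train_fraction, cfg$seed)
      n <- stats::setNames(rep(cfg$tasks$n_augment, length(ck$label_levels)),
                           ck$label_levels)
      syn <- augment(ck, n, seed = cfg$seed, scale = "normalized")
      report <- build_eval_report(
        pp$train, pp$test,
        stats::setNames(list(syn), as.character(ncol(syn$values))))
      utils::write.table(report, .cfg_path(cfg, "eval_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(report = report)
    })
  .write_manifest(cfg, stage, list(seed = cfg$seed))
  invisible(out)
}
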