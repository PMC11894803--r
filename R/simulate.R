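#' Specification for a two-phenotype synthetic expression matrix
#'
#' Describes a log-normal generative scheme: each gene gets a baseline mean
#' drawn uniformly (in log2 units) from `base_mean_range`; log2 expression is
#' Gaussian around that mean with sd `noise_sd`; in samples of the "tumor"
#' class the first `n_signal` genes have their mean shifted by `effect_size`
#' log2 units. Values are mapped back to an FPKM-like scale as `2^x - 1`
#' (clipped at 0), so the standard `log2(n+1)` preprocessing recovers the
#' Gaussian structure.
#'
#' @param n_per_class samples per phenotype class (>= 1).
#' @param n_genes number of genes.
#' @param n_signal number of planted signal genes (0..n_genes); these are the
#'   first `n_signal` gene ids.
#' @param effect_size mean shift, in log2 units, applied to signal genes in
#'   the tumor class.
#' @param base_mean_range length-2 numeric, uniform range of baseline log2
#'   means (default 2..10, a typical span of expressed-gene abundances).
#' @param noise_sd per-gene Gaussian sd in log2 space (> 0, default 1).
#' @param seed integer RNG seed; identical specs give bit-identical data.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class, n_genes, n_signal, effect_size,
                           base_mean_range = c(2, 10), noise_sd = 1,
                           seed = 1L) {
  s <- structure(list(n_per_class = as.integer(n_per_class),
                      n_genes = as.integer(n_genes),
                      n_signal = as.integer(n_signal),
                      effect_size = as.numeric(effect_size),
                      base_mean_range = as.numeric(base_mean_range),
                      noise_sd = as.numeric(noise_sd),
                      seed = as.integer(seed)),
                 class = "synthetic_spec")
  if (s$n_per_class < 1) stop("invalid spec: n_per_class must be >= 1")
  if (s$n_genes < 1) stop("invalid spec: n_genes must be >= 1")
  if (s$n_signal < 0 || s$n_signal > s$n_genes)
    stop("invalid spec: n_signal must be in 0..n_genes")
  if (s$noise_sd <= 0) stop("invalid spec: noise_sd must be > 0")
  if (length(s$base_mean_range) != 2 || diff(s$base_mean_range) < 0)
    stop("invalid spec: base_mean_range must be an increasing pair")
  s
}

#' Generate a two-phenotype GEM with planted signal genes
#'
#' The workhorse fixture generator: every downstream stage (screening,
#' diffusion training, perturbation, evaluation) can be validated against the
#' known planted genes. Sample ids are `normal_1..n` and `tumor_1..n`; gene
#' ids are `sig_1..n_signal` followed by `null_1..`.
#'
#' @param spec a [synthetic_spec].
#' @return list with elements `gem` (a labeled [gem] on the FPKM-like scale)
#'   and `signal_genes` (character vector of planted gene ids).
#' @export
generate_two_state_gem <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    G <- spec$n_genes; n <- spec$n_per_class
    mu <- stats::runif(G, spec$base_mean_range[1], spec$base_mean_range[2])
    gene_ids <- c(if (spec$n_signal > 0) paste0("sig_", seq_len(spec$n_signal)),
                  if (G > spec$n_signal) paste0("null_", seq_len(G - spec$n_signal)))
    shift <- c(rep(spec$effect_size, spec$n_signal), rep(0, G - spec$n_signal))
    logx_normal <- matrix(stats::rnorm(n * G, mean = rep(mu, each = n),
                                       sd = spec$noise_sd), n, G)
    logx_tumor <- matrix(stats::rnorm(n * G, mean = rep(mu + shift, each = n),
                                      sd = spec$noise_sd), n, G)
    vals <- pmax(2^rbind(logx_normal, logx_tumor) - 1, 0)
    dimnames(vals) <- list(c(paste0("normal_", seq_len(n)),
                             paste0("tumor_", seq_len(n))), gene_ids)
    list(gem = gem(vals, labels = rep(c("normal", "tumor"), each = n)),
         signal_genes = gene_ids[seq_len(spec$n_signal)])
  })
}

#' Generate disjoint named gene sets of given sizes
#'
#' A seeded fixture standing in for curated gene-set collections: gene ids
#' are shuffled and carved into disjoint sets of the requested sizes.
#'
#' @param gene_ids pool of gene identifiers.
#' @param set_sizes integer vector of set sizes; their sum must not exceed
#'   the pool size.
#' @param seed integer RNG seed.
#' @return named list of character vectors (`set_1`, `set_2`, ...),
#'   writable with [write_gmt()].
#' @export
generate_gene_set_collection <- function(gene_ids, set_sizes, seed = 1L) {
  set_sizes <- as.integer(set_sizes)
  if (any(set_sizes < 1)) stop("set sizes must be positive")
  if (sum(set_sizes) > length(gene_ids))
    stop(sprintf("requested %d genes but only %d available",
                 sum(set_sizes), length(gene_ids)))
  withr::with_seed(seed, {
    pool <- sample(gene_ids)
    ends <- cumsum(set_sizes)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    sets <- Map(function(a, b) pool[a:b], starts, ends)
    stats::setNames(sets, paste0("set_", seq_along(sets)))
  })
}
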