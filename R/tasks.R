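#' Augment expression data by sampling from noise
#'
#' Draws ancestral (stochastic reverse-chain) samples per phenotype label
#' from a trained checkpoint and maps them back through the stored scaler
#' and the inverse log2 transform to the original FPKM-like scale.
#'
#' @param checkpoint a list from [load_checkpoint()] (or the same structure
#'   built in memory).
#' @param n_per_label named integer vector / list, e.g.
#'   `c(normal = 100, tumor = 100)`.
#' @param seed integer RNG seed.
#' @param scale `"fpkm"` (default) or `"normalized"` to keep the \[-1, 1\]
#'   model space.
#' @return a labeled synthetic [gem].
#' @export
augment <- function(checkpoint, n_per_label, seed = 1L,
                    scale = c("fpkm", "normalized")) {
  scale <- match.arg(scale)
  levels <- checkpoint$label_levels
  unknown <- setdiff(names(n_per_label), levels)
  if (length(unknown))
    stop("unknown label(s): ", paste(unknown, collapse = ", "),
         " (model knows: ", paste(levels, collapse = ", "), ")")
  dn <- denoiser_fun(checkpoint$model)
  G <- checkpoint$model$n_genes
  out <- list(); labs <- character()
  for (i in seq_along(n_per_label)) {
    lab <- names(n_per_label)[i]
    k <- as.integer(n_per_label[[i]])
    if (k < 1) next
    x <- ancestral_sample(dn, k, G, match(lab, levels), checkpoint$schedule,
                          seed = as.integer(seed) + i)
    out[[lab]] <- x
    labs <- c(labs, rep(lab, k))
  }
  vals <- do.call(rbind, out)
  colnames(vals) <- checkpoint$gene_ids
  rownames(vals) <- paste0("synthetic_", seq_len(nrow(vals)))
  g <- gem(vals, labels = labs)
  if (scale == "fpkm") invert_scaler(g, checkpoint$scaler, to_fpkm = TRUE)
  else g
}

#' Perturb samples from one phenotype state to another
#'
#' The state-transfer bridge: source-state rows are encoded to the step-T
#' latent along the deterministic ODE under the source condition, then
#' decoded under the target condition. Per-gene signed perturbation scores
#' are the mean over samples of (perturbed - original) in normalized
#' space; the direction is the sign of the score.
#'
#' @param checkpoint a trained checkpoint (see [load_checkpoint()]); must
#'   have been trained on exactly the genes of `g`.
#' @param g a labeled [gem] on the original FPKM-like scale containing the
#'   source-state samples (rows with other labels are dropped).
#' @param source_label,target_label phenotype labels, both in the
#'   checkpoint vocabulary.
#' @param n_ode_steps ODE integration steps (default 100).
#' @param subset_name identity recorded on the result (default `"genes"`).
#' @return object of class `perturbation_result`: list with `original`,
#'   `perturbed` (normalized, row-paired matrices), `per_gene_score`,
#'   `per_gene_direction`, `subset_name`, plus `original_fpkm` /
#'   `perturbed_fpkm` on the original scale.
#' @export
perturb <- function(checkpoint, g, source_label, target_label,
                    n_ode_steps = 100L, subset_name = "genes") {
  stopifnot(is.gem(g))
  levels <- checkpoint$label_levels
  for (lab in c(source_label, target_label))
    if (!lab %in% levels)
      stop("label '", lab, "' unknown to the checkpoint (knows: ",
           paste(levels, collapse = ", "), ")")
  if (!identical(colnames(g$values), checkpoint$gene_ids)) {
    if (!setequal(colnames(g$values), checkpoint$gene_ids))
      stop("gene set does not match the checkpoint")
    g <- gem_subset(g, genes = checkpoint$gene_ids)
  }
  if (is.null(g$labels)) stop("input GEM must be labeled")
  keep <- g$labels == source_label
  if (!any(keep)) stop("no samples with source label '", source_label, "'")
  g <- gem(g$values[keep, , drop = FALSE], labels = g$labels[keep])
  x_norm <- apply_scaler(log2p1(g), checkpoint$scaler)$values
  dn <- denoiser_fun(checkpoint$model)
  latent <- ode_encode(dn, x_norm, match(source_label, levels),
                       checkpoint$schedule, n_ode_steps)
  x_pert <- ode_decode(dn, latent, match(target_label, levels),
                       checkpoint$schedule, n_ode_steps)
  dimnames(x_pert) <- dimnames(x_norm)
  score <- colMeans(x_pert - x_norm)
  structure(list(original = x_norm, perturbed = x_pert,
                 per_gene_score = score,
                 per_gene_direction = sign(score),
                 subset_name = subset_name,
                 source_label = source_label, target_label = target_label,
                 original_fpkm = invert_scaler(x_norm, checkpoint$scaler,
                                               to_fpkm = TRUE),
                 perturbed_fpkm = invert_scaler(x_pert, checkpoint$scaler,
                                                to_fpkm = TRUE)),
            class = "perturbation_result")
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(sprintf("perturbation %s -> %s: %d samples x %d genes (subset '%s')\n",
              x$source_label, x$target_label, nrow(x$original),
              ncol(x$original), x$subset_name))
  cat("top |score| genes:",
      paste(utils::head(names(sort(-abs(x$per_gene_score))), 5),
            collapse = ", "), "\n")
  invisible(x)
}

#' Pool perturbation scores and call core genes
#'
#' Combines per-gene scores across disjoint subsets into one distribution
#' and flags as "core" the genes whose score lies strictly beyond
#' `k_sd` population standard deviations from the pooled mean (two-sided).
#'
#' @param results list of `perturbation_result` objects with pairwise
#'   disjoint gene sets.
#' @param k_sd threshold width (default 2).
#' @return data.frame (class `core_gene_table`) with columns `gene`,
#'   `score`, `direction`, `z`, `core`, sorted by decreasing `|z|`.
#' @export
pool_scores <- function(results, k_sd = 2) {
  if (inherits(results, "perturbation_result")) results <- list(results)
  genes <- unlist(lapply(results, function(r) names(r$per_gene_score)),
                  use.names = FALSE)
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("gene(s) appear in more than one subset: ",
         paste(dup, collapse = ", "))
  score <- unlist(lapply(results, `[[`, "per_gene_score"), use.names = FALSE)
  subset <- unlist(lapply(results, function(r)
    rep(r$subset_name, length(r$per_gene_score))), use.names = FALSE)
  m <- mean(score)
  s <- sqrt(mean((score - m)^2))
  z <- if (s > 0) (score - m) / s else rep(0, length(score))
  tab <- data.frame(gene = genes, subset = subset, score = score,
                    direction = sign(score), z = z,
                    core = abs(score - m) > k_sd * s,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-abs(tab$z)), ]
  rownames(tab) <- NULL
  attr(tab, "score_mean") <- m
  attr(tab, "score_sd") <- s
  class(tab) <- c("core_gene_table", class(tab))
  tab
}

#' Pearson correlation between perturbation magnitude and silhouette
#'
#' The workflow-level association check: across gene subsets, does the mean
#' absolute perturbation track the subset's cluster-separation silhouette?
#'
#' @param subset_mean_abs_scores numeric vector (one value per subset).
#' @param silhouettes numeric vector of the same length (>= 3).
#' @return Pearson correlation coefficient.
#' @export
correlate_perturbation_silhouette <- function(subset_mean_abs_scores,
                                              silhouettes) {
  x <- as.numeric(subset_mean_abs_scores); y <- as.numeric(silhouettes)
  if (length(x) != length(y) || length(x) < 3)
    stop("need two equal-length vectors with at least 3 entries")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance in input")
  stats::cor(x, y)
}

#' Hypergeometric over-representation test with Benjamini-Yekutieli FDR
#'
#' For each annotation set, the one-sided hypergeometric tail probability
#' of observing at least the seen overlap between the query and the set
#' (both restricted to the background universe), adjusted across sets with
#' the Benjamini-Yekutieli procedure (valid under arbitrary dependence).
#'
#' @param query_genes character vector (must be a subset of `background`).
#' @param annotation_sets named list of character vectors (e.g. from
#'   [read_gmt()]); genes outside the background are ignored.
#' @param background character vector: the gene universe.
#' @param q_threshold rows with `q` below this are flagged `significant`
#'   (default 1e-10, the conventional stringent cutoff for large curated
#'   collections).
#' @return data.frame with columns `set`, `set_size`, `overlap`, `p`, `q`,
#'   `significant`, sorted by `p`.
#' @export
enrich <- function(query_genes, annotation_sets, background,
                   q_threshold = 1e-10) {
  background <- unique(as.character(background))
  if (!length(background)) stop("background must be non-empty")
  query_genes <- unique(as.character(query_genes))
  out <- setdiff(query_genes, background)
  if (length(out))
    stop("query genes not in background: ", paste(out, collapse = ", "))
  N <- length(background); k <- length(query_genes)
  rows <- lapply(names(annotation_sets), function(nm) {
    set <- intersect(annotation_sets[[nm]], background)
    ov <- length(intersect(set, query_genes))
    p <- stats::phyper(ov - 1, length(set), N - length(set), k,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set), overlap = ov, p = p)
  })
  tab <- do.call(rbind, rows)
  tab$q <- stats::p.adjust(tab$p, method = "BY")
  tab$significant <- tab$q < q_threshold
  tab <- tab[order(tab$p), ]
  rownames(tab) <- NULL
  tab
}

#' Write perturbation artifacts as TSV
#'
#' Emits the paired original/perturbed matrices (original FPKM-like scale)
#' and the per-gene score table.
#'
#' @param result a `perturbation_result`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default the subset name).
#' @return invisibly, the written paths.
#' @export
write_perturbation <- function(result, dir, prefix = result$subset_name) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, paste0(prefix, "_original.tsv"))
  p2 <- file.path(dir, paste0(prefix, "_perturbed.tsv"))
  p3 <- file.path(dir, paste0(prefix, "_scores.tsv"))
  utils::write.table(data.frame(sample = rownames(result$original_fpkm),
                                result$original_fpkm, check.names = FALSE),
                     p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = rownames(result$perturbed_fpkm),
                                result$perturbed_fpkm, check.names = FALSE),
                     p2, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = names(result$per_gene_score),
                                score = unname(result$per_gene_score),
                                direction = unname(result$per_gene_direction)),
                     p3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
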