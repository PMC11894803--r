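#' Partition a gene list into disjoint fixed-size subsets
#'
#' Genes are shuffled with the seed and carved into consecutive blocks of
#' `subset_size`; a final incomplete block is dropped so every subset has
#' exactly `subset_size` genes.
#'
#' @param genes character vector of gene ids.
#' @param subset_size subset size (>= 1); the published workflow uses 16.
#' @param seed integer RNG seed.
#' @param parent_set_name name recorded on each subset (default `"genes"`).
#' @return list of `gene_subset` objects (possibly empty), each with fields
#'   `parent_set_name`, `subset_index`, `gene_ids`.
#' @export
partition_gene_set <- function(genes, subset_size, seed = 1L,
                               parent_set_name = "genes") {
  subset_size <- as.integer(subset_size)
  if (subset_size < 1) stop("subset_size must be >= 1")
  if (!length(genes)) return(list())
  k <- length(genes) %/% subset_size
  if (k == 0) return(list())
  shuffled <- withr::with_seed(as.integer(seed), sample(genes))
  lapply(seq_len(k), function(i) {
    structure(list(parent_set_name = parent_set_name, subset_index = i,
                   gene_ids = shuffled[((i - 1) * subset_size + 1):(i * subset_size)]),
              class = "gene_subset")
  })
}

.find_python <- function() {
  py <- getOption("phenobridge.python", Sys.which("python"))
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("no 'python' interpreter found on PATH; ",
                        "UMAP embedding requires python with umap-learn")
  py
}

# Embed a list of samples x features matrices in 2-D with UMAP, one python
# subprocess for the whole batch.
.umap_batch <- function(matrices, n_neighbors, min_dist, seed) {
  stopifnot(length(matrices) >= 1)
  n_min <- min(vapply(matrices, nrow, 1L))
  if (n_neighbors >= n_min) {
    warning(sprintf("n_neighbors reduced from %d to %d (samples - 1)",
                    n_neighbors, n_min - 1L))
    n_neighbors <- n_min - 1L
  }
  script <- system.file("python", "umap_embed.py", package = "phenobridge",
                        mustWork = TRUE)
  infile <- tempfile(fileext = ".json"); outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(list(n_neighbors = n_neighbors, min_dist = min_dist,
                            seed = as.integer(seed),
                            matrices = lapply(matrices, unname)),
                       infile, auto_unbox = TRUE, digits = NA)
  status <- system2(.find_python(), c(script, infile, outfile),
                    stdout = FALSE, stderr = "")
  if (status != 0 || !file.exists(outfile))
    stop("UMAP embedding subprocess failed (exit status ", status, ")")
  # no simplification: equal-shaped matrices must stay a list, not an array
  lapply(jsonlite::read_json(outfile, simplifyVector = FALSE), function(m) {
    do.call(rbind, lapply(m, function(row) as.numeric(unlist(row))))
  })
}

#' 2-D UMAP embedding of a sample matrix
#'
#' Delegates to the reference `umap-learn` implementation (Python
#' subprocess) with a fixed random state, so identical inputs and seed give
#' identical coordinates. Defaults `n_neighbors = 90`, `min_dist = 0.3`
#' represent generalized local and global structure in bulk expression
#' data; `n_neighbors` is reduced to `samples - 1` with a warning when the
#' matrix is small.
#'
#' @param x numeric matrix, samples x features.
#' @param n_neighbors UMAP neighborhood size (default 90).
#' @param min_dist minimum embedded distance (default 0.3).
#' @param seed integer random state.
#' @return samples x 2 coordinate matrix.
#' @export
embed_2d <- function(x, n_neighbors = 90L, min_dist = 0.3, seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 samples to embed")
  .umap_batch(list(x), n_neighbors, min_dist, seed)[[1]]
}

#' Mean silhouette score of labeled 2-D coordinates
#'
#' Classical silhouette: for sample i, `a(i)` is the mean Euclidean
#' distance to the other members of its own cluster (0 for singleton
#' clusters), `b(i)` the minimum over other clusters of the mean distance
#' to that cluster's members, and `s(i) = (b - a) / max(a, b)`. Returns the
#' mean over samples, always in \[-1, 1\].
#'
#' @param coords samples x d numeric matrix (2-D in this workflow).
#' @param labels cluster/phenotype label per sample (>= 2 distinct values).
#' @return mean silhouette score.
#' @export
silhouette_score <- function(coords, labels) {
  coords <- as.matrix(coords)
  labels <- as.character(labels)
  if (length(labels) != nrow(coords)) stop("one label per sample required")
  lev <- unique(labels)
  if (length(lev) < 2) stop("silhouette needs at least two clusters")
  D <- as.matrix(stats::dist(coords))
  n <- nrow(coords)
  s <- numeric(n)
  idx_by <- split(seq_len(n), labels)
  for (i in seq_len(n)) {
    own <- idx_by[[labels[i]]]
    if (length(own) == 1) { s[i] <- 0; next }
    a <- sum(D[i, own]) / (length(own) - 1)
    b <- min(vapply(idx_by[names(idx_by) != labels[i]],
                    function(j) mean(D[i, j]), 1.0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Score gene subsets by cluster separation on a 2-D embedding
#'
#' For each subset the GEM (already preprocessed to the \[-1, 1\] scale) is
#' restricted to the subset's genes, embedded in 2-D with UMAP, and the
#' phenotype-label silhouette of the embedding is computed. All subsets are
#' embedded in one batched call.
#'
#' @param g a labeled, preprocessed [gem].
#' @param subsets list of `gene_subset` objects (see
#'   [partition_gene_set()]).
#' @param n_neighbors,min_dist,seed embedding parameters, see [embed_2d()].
#' @return data.frame (class `screen_result`) with columns `parent_set`,
#'   `subset_index`, `genes` (comma-joined), `silhouette`, `selected`
#'   (`"neither"` until [select_extremes()] is applied).
#' @export
screen_subsets <- function(g, subsets, n_neighbors = 90L, min_dist = 0.3,
                           seed = 1L) {
  stopifnot(is.gem(g), length(subsets) >= 1)
  if (is.null(g$labels)) stop("screening requires phenotype labels")
  for (s in subsets) {
    miss <- setdiff(s$gene_ids, colnames(g$values))
    if (length(miss))
      stop(sprintf("subset %s/%d: gene(s) not in GEM: %s",
                   s$parent_set_name, s$subset_index,
                   paste(miss, collapse = ", ")))
  }
  mats <- lapply(subsets, function(s) g$values[, s$gene_ids, drop = FALSE])
  embeds <- .umap_batch(mats, n_neighbors, min_dist, seed)
  sil <- vapply(embeds, silhouette_score, 1.0, labels = g$labels)
  res <- data.frame(
    parent_set = vapply(subsets, `[[`, "", "parent_set_name"),
    subset_index = vapply(subsets, `[[`, 1L, "subset_index"),
    genes = vapply(subsets, function(s) paste(s$gene_ids, collapse = ","), ""),
    silhouette = sil,
    selected = "neither",
    stringsAsFactors = FALSE)
  class(res) <- c("screen_result", class(res))
  res
}

#' Flag high / low cluster-potential subsets
#'
#' Computes the mean and population standard deviation of the silhouette
#' scores over all screened subsets and flags scores strictly above
#' `mean + k_sd * sd` as `"high"` and strictly below `mean - k_sd * sd` as
#' `"low"`.
#'
#' @param results a `screen_result` data.frame (>= 2 rows).
#' @param k_sd threshold width in standard deviations (default 1).
#' @return the input with the `selected` column filled in; attributes
#'   `sil_mean` and `sil_sd` record the thresholds' ingredients.
#' @export
select_extremes <- function(results, k_sd = 1) {
  if (nrow(results) < 2) stop("need at least two screened subsets")
  x <- results$silhouette
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))   # population sd: thresholding a census
  results$selected <- ifelse(x > m + k_sd * s, "high",
                             ifelse(x < m - k_sd * s, "low", "neither"))
  attr(results, "sil_mean") <- m
  attr(results, "sil_sd") <- s
  results
}

#' Silhouette background from random gene draws
#'
#' Draws `n_reps` random gene subsets (without replacement within a draw)
#' from a pool, screens each, and returns the mean and standard deviation
#' of their silhouettes — the random-background control against which
#' targeted gene sets are compared.
#'
#' @param g a labeled, preprocessed [gem].
#' @param subset_size genes per draw.
#' @param n_reps number of draws (>= 2).
#' @param seed integer RNG seed.
#' @param pool optional character vector restricting the genes drawn from
#'   (default: all genes in `g`).
#' @param n_neighbors,min_dist embedding parameters.
#' @return list with `mean`, `sd` (sample sd over draws) and the per-draw
#'   `silhouettes`.
#' @export
random_background <- function(g, subset_size, n_reps, seed = 1L,
                              pool = NULL, n_neighbors = 90L,
                              min_dist = 0.3) {
  stopifnot(is.gem(g))
  if (n_reps < 2) stop("n_reps must be >= 2")
  if (is.null(pool)) pool <- colnames(g$values)
  if (subset_size > length(pool)) stop("subset_size exceeds the gene pool")
  draws <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_reps), function(i) sample(pool, subset_size))
  })
  subsets <- lapply(seq_along(draws), function(i) {
    structure(list(parent_set_name = "random_background", subset_index = i,
                   gene_ids = draws[[i]]), class = "gene_subset")
  })
  res <- screen_subsets(g, subsets, n_neighbors, min_dist, seed)
  list(mean = mean(res$silhouette), sd = stats::sd(res$silhouette),
       silhouettes = res$silhouette)
}

#' Write a screening report as TSV
#'
#' @param results a `screen_result` data.frame.
#' @param path output path.
#' @export
write_screen_report <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
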