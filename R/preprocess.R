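#' log2(n + 1) transform
#'
#' The `+1` keeps unexpressed genes (zeros) at exactly zero instead of
#' negative infinity.
#'
#' @param g a [gem] with non-negative values.
#' @return a [gem] on the log2 scale.
#' @export
log2p1 <- function(g) {
  stopifnot(is.gem(g))
  neg <- which(g$values < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative value at sample '%s', gene '%s'",
                 rownames(g$values)[neg[1, 1]], colnames(g$values)[neg[1, 2]]))
  gem(log2(g$values + 1), labels = g$labels)
}

#' Fit a per-gene min-max scaler targeting (-1, 1)
#'
#' Records each gene's minimum and maximum on the fitting data (already
#' log2(n+1)-transformed). Genes whose min equals max are flagged constant
#' and later mapped to the interval midpoint 0. Fit the scaler on the
#' training split only, so no information leaks from held-out data.
#'
#' @param g a [gem] on the log2 scale.
#' @return an object of class `scaler_params` with fields `gene_ids`, `min`,
#'   `max`, `constant`, `lo`, `hi`.
#' @export
fit_scaler <- function(g) {
  stopifnot(is.gem(g))
  mn <- apply(g$values, 2, min)
  mx <- apply(g$values, 2, max)
  structure(list(gene_ids = colnames(g$values), min = unname(mn),
                 max = unname(mx), constant = unname(mx == mn),
                 lo = -1, hi = 1),
            class = "scaler_params")
}

.match_scaler <- function(p, gene_ids) {
  idx <- match(gene_ids, p$gene_ids)
  if (anyNA(idx))
    stop("genes not in scaler: ", paste(gene_ids[is.na(idx)], collapse = ", "))
  idx
}

#' Apply a fitted min-max scaler
#'
#' Maps each gene affinely so that the fitted min/max land on -1/+1. Values
#' outside the fitted range (new data) are clipped to \[-1, 1\]; constant
#' genes map to 0.
#'
#' @param g a [gem] on the log2 scale.
#' @param params a `scaler_params` from [fit_scaler()].
#' @return a [gem] with values in \[-1, 1\].
#' @export
apply_scaler <- function(g, params) {
  stopifnot(is.gem(g), inherits(params, "scaler_params"))
  idx <- .match_scaler(params, colnames(g$values))
  mn <- params$min[idx]; mx <- params$max[idx]
  rng <- mx - mn
  rng[rng == 0] <- 1  # constant genes handled below
  v <- sweep(sweep(g$values, 2, mn, "-"), 2, rng, "/") * 2 - 1
  if (any(params$constant[idx])) v[, params$constant[idx]] <- 0
  v <- pmin(pmax(v, -1), 1)
  gem(v, labels = g$labels)
}

#' Invert the min-max scaler (and optionally the log2 transform)
#'
#' Algebraic inverse of [apply_scaler()]: exact to numerical precision for
#' non-constant genes whose values were not clipped; constant genes are
#' restored to their fitted constant. With `to_fpkm = TRUE` the result is
#' further mapped through `2^v - 1` (clipped at 0) back to the original
#' expression scale.
#'
#' @param m numeric matrix (samples x genes, columns named) in \[-1, 1\], or
#'   a [gem].
#' @param params a `scaler_params`.
#' @param to_fpkm also undo the log2(n+1) transform (default `FALSE`).
#' @return matrix or [gem] (matching the input type) on the log2 or
#'   FPKM-like scale.
#' @export
invert_scaler <- function(m, params, to_fpkm = FALSE) {
  was_gem <- is.gem(m)
  labels <- if (was_gem) m$labels else NULL
  v <- if (was_gem) m$values else as.matrix(m)
  idx <- .match_scaler(params, colnames(v))
  mn <- params$min[idx]; mx <- params$max[idx]
  out <- sweep(sweep((v + 1) / 2, 2, mx - mn, "*"), 2, mn, "+")
  if (any(params$constant[idx]))
    out[, params$constant[idx]] <- rep(mn[params$constant[idx]],
                                       each = nrow(out))
  if (to_fpkm) out <- pmax(2^out - 1, 0)
  if (was_gem) gem(out, labels = labels) else out
}

#' Serialize / read scaler parameters as TSV
#'
#' Three columns: gene, min, max. Keeping this on disk lets perturbation
#' outputs be un-scaled reproducibly in a later process.
#'
#' @param params a `scaler_params`.
#' @param path file path.
#' @export
write_scaler <- function(params, path) {
  utils::write.table(data.frame(gene = params$gene_ids, min = params$min,
                                max = params$max),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scaler
#' @export
read_scaler <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "numeric", "numeric"))
  structure(list(gene_ids = tab$gene, min = tab$min, max = tab$max,
                 constant = tab$max == tab$min, lo = -1, hi = 1),
            class = "scaler_params")
}

#' Stratified train/test split
#'
#' Deterministic given the seed. The train size is `floor(train_fraction * n)`;
#' under stratification the train quota is apportioned across labels by
#' largest remainder, so per-label proportions are preserved to within one
#' sample.
#'
#' @param g a [gem] (labeled if `stratify = TRUE`).
#' @param train_fraction fraction in (0, 1); the published workflow uses 0.67.
#' @param seed integer RNG seed.
#' @param stratify preserve label proportions (default `TRUE`).
#' @return list with elements `train` and `test`, both [gem]s; the split is
#'   disjoint and exhaustive.
#' @export
split_train_test <- function(g, train_fraction = 0.67, seed = 1L,
                             stratify = TRUE) {
  stopifnot(is.gem(g))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n <- nrow(g$values)
  n_train <- floor(train_fraction * n)
  withr::with_seed(seed, {
    if (stratify) {
      if (is.null(g$labels)) stop("stratified split requires labels")
      tb <- table(g$labels)
      if (any(tb < 2))
        stop("every label needs >= 2 samples for a stratified split: ",
             paste(names(tb)[tb < 2], collapse = ", "))
      quota <- train_fraction * as.numeric(tb)
      base <- floor(quota)
      rem <- n_train - sum(base)
      if (rem > 0) {
        ord <- order(quota - base, decreasing = TRUE)
        base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
      }
      idx_train <- unlist(Map(function(lab, k) {
        sample(which(g$labels == lab))[seq_len(k)]
      }, names(tb), base), use.names = FALSE)
    } else {
      idx_train <- sample(n)[seq_len(n_train)]
    }
    idx_train <- sort(idx_train)
    idx_test <- setdiff(seq_len(n), idx_train)
    list(train = gem(g$values[idx_train, , drop = FALSE],
                     labels = g$labels[idx_train]),
         test = gem(g$values[idx_test, , drop = FALSE],
                    labels = g$labels[idx_test]))
  })
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper: log2(n+1), stratified split, scaler fit on the train
#' split, scaling (with clipping) of both splits.
#'
#' @inheritParams split_train_test
#' @return list with `train`, `test` (scaled [gem]s) and `scaler`.
#' @export
preprocess_gem <- function(g, train_fraction = 0.67, seed = 1L,
                           stratify = TRUE) {
  lg <- log2p1(g)
  sp <- split_train_test(lg, train_fraction, seed, stratify)
  scaler <- fit_scaler(sp$train)
  list(train = apply_scaler(sp$train, scaler),
       test = apply_scaler(sp$test, scaler),
       scaler = scaler)
}
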