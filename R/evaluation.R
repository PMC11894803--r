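#' Maximum mean discrepancy with a Gaussian kernel
#'
#' Biased (V-statistic) estimator,
#' `mean k(X,X) + mean k(Y,Y) - 2 mean k(X,Y)` with
#' `k(x,y) = exp(-||x-y||^2 / (2 sigma^2))`; including the diagonal terms
#' keeps the estimate non-negative. `sigma = "median"` (the default) uses
#' the median of the off-diagonal pairwise distances of the pooled sample.
#'
#' @param X,Y numeric matrices with the same number of columns.
#' @param sigma positive bandwidth, or `"median"`.
#' @return non-negative scalar; 0 when `X` and `Y` are identical.
#' @export
mmd <- function(X, Y, sigma = "median") {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("X and Y must have the same number of columns")
  n <- nrow(X); m <- nrow(Y)
  if (n < 1 || m < 1) stop("X and Y need at least one row each")
  D <- as.matrix(stats::dist(rbind(X, Y)))
  if (identical(sigma, "median")) {
    off <- D[upper.tri(D)]
    sigma <- stats::median(off)
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  }
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  K <- exp(-D^2 / (2 * sigma^2))
  kxx <- mean(K[seq_len(n), seq_len(n)])
  kyy <- mean(K[n + seq_len(m), n + seq_len(m)])
  kxy <- mean(K[seq_len(n), n + seq_len(m)])
  max(kxx + kyy - 2 * kxy, 0)
}

#' Phenotype classification accuracy of an RBF-kernel SVM
#'
#' Trains a support-vector classifier (radial basis kernel, `C = 1`,
#' `gamma = 1 / (d * Var(train values))`) on the training GEM and reports
#' percent accuracy on the evaluation GEM. Deterministic given the inputs.
#'
#' @param train_gem labeled [gem] used for fitting (>= 2 classes).
#' @param eval_gem labeled [gem] scored against its own labels.
#' @return accuracy in percent (0..100).
#' @export
classifier_accuracy <- function(train_gem, eval_gem) {
  stopifnot(is.gem(train_gem), is.gem(eval_gem))
  if (is.null(train_gem$labels) || is.null(eval_gem$labels))
    stop("both GEMs must be labeled")
  if (length(unique(train_gem$labels)) < 2)
    stop("training data has a single class")
  genes <- colnames(train_gem$values)
  if (!setequal(genes, colnames(eval_gem$values)))
    stop("train and eval GEMs must share the same gene set")
  xe <- eval_gem$values[, genes, drop = FALSE]
  xt <- train_gem$values
  gamma <- 1 / (ncol(xt) * stats::var(as.vector(xt)))
  fit <- e1071::svm(x = xt, y = factor(train_gem$labels), kernel = "radial",
                    cost = 1, gamma = gamma, scale = FALSE)
  pred <- stats::predict(fit, xe)
  100 * mean(as.character(pred) == eval_gem$labels)
}

#' Build an augmentation evaluation report
#'
#' Mirrors the standard generative-model evaluation protocol: the baseline
#' row is `MMD(test, train)` plus the accuracy of an SVM trained on the
#' train split and scored on the test split; each model row (one per gene
#' feature size) is `MMD(synthetic, test)` plus the accuracy of the same
#' train-fitted SVM scored on the synthetic data with its intended labels.
#'
#' @param train,test labeled [gem]s (preprocessed scale).
#' @param synthetic_by_size named list mapping feature size (as character)
#'   to a labeled synthetic [gem]; each synthetic GEM's genes must be a
#'   subset of the train genes.
#' @param sigma MMD kernel bandwidth (default `"median"`).
#' @return data.frame with columns `feature_size`, `baseline_mmd`,
#'   `baseline_acc`, `model_mmd`, `model_acc` (baseline row first,
#'   `feature_size = NA` entries filled with the full train width).
#' @export
build_eval_report <- function(train, test, synthetic_by_size,
                              sigma = "median") {
  stopifnot(is.gem(train), is.gem(test))
  base_mmd <- mmd(test$values, train$values, sigma)
  base_acc <- classifier_accuracy(train, test)
  rows <- list(data.frame(feature_size = ncol(train$values),
                          baseline_mmd = base_mmd, baseline_acc = base_acc,
                          model_mmd = NA_real_, model_acc = NA_real_))
  for (sz in names(synthetic_by_size)) {
    syn <- synthetic_by_size[[sz]]
    genes <- colnames(syn$values)
    tr <- gem_subset(train, genes = genes)
    te <- gem_subset(test, genes = genes)
    rows[[length(rows) + 1]] <- data.frame(
      feature_size = as.integer(sz),
      baseline_mmd = mmd(te$values, tr$values, sigma),
      baseline_acc = classifier_accuracy(tr, te),
      model_mmd = mmd(syn$values, te$values, sigma),
      model_acc = classifier_accuracy(tr, syn))
  }
  do.call(rbind, rows)
}
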