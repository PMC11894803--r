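#' Construct a gene expression matrix (GEM) object
#'
#' A `gem` holds a samples x genes numeric matrix together with unique sample
#' and gene identifiers and, optionally, a per-sample phenotype label. The
#' samples-are-rows orientation is fixed internally because rows are the data
#' points consumed by the diffusion model.
#'
#' @param values numeric matrix, samples in rows, genes in columns.
#' @param gene_ids character vector of unique gene identifiers (column names).
#' @param sample_ids character vector of unique sample identifiers (row names).
#' @param labels optional character/factor vector of per-sample phenotype
#'   labels (e.g. `"normal"` / `"tumor"`).
#' @return an object of class `gem`.
#' @export
gem <- function(values, gene_ids = colnames(values),
                sample_ids = rownames(values), labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene_ids and sample_ids are required (or set dimnames on 'values')")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != ncol(values))
    stop("length(gene_ids) != number of gene columns")
  if (length(sample_ids) != nrow(values))
    stop("length(sample_ids) != number of sample rows")
  .check_unique(gene_ids, "gene id")
  .check_unique(sample_ids, "sample id")
  dimnames(values) <- list(sample_ids, gene_ids)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(values))
      stop("labels must have one entry per sample")
  }
  structure(list(values = values, labels = labels), class = "gem")
}

.check_unique <- function(x, what) {
  d <- unique(x[duplicated(x)])
  if (length(d))
    stop(sprintf("duplicate %ss: %s", what, paste(d, collapse = ", ")))
  invisible(x)
}

#' @export
print.gem <- function(x, ...) {
  cat(sprintf("gem: %d samples x %d genes\n", nrow(x$values), ncol(x$values)))
  if (!is.null(x$labels)) {
    tb <- table(x$labels)
    cat("labels:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  } else cat("labels: <none>\n")
  invisible(x)
}

#' @export
dim.gem <- function(x) dim(x$values)

#' @rdname gem
#' @param x object to test.
#' @export
is.gem <- function(x) inherits(x, "gem")

gene_ids <- function(g) colnames(g$values)
sample_ids <- function(g) rownames(g$values)

#' Subset a GEM to named genes and/or samples
#'
#' @param g a [gem].
#' @param genes character vector of gene ids to keep (order preserved as
#'   given); `NULL` keeps all.
#' @param samples character vector of sample ids to keep; `NULL` keeps all.
#' @return a [gem].
#' @export
gem_subset <- function(g, genes = NULL, samples = NULL) {
  stopifnot(is.gem(g))
  v <- g$values
  lab <- g$labels
  if (!is.null(samples)) {
    miss <- setdiff(samples, rownames(v))
    if (length(miss)) stop("unknown sample ids: ", paste(miss, collapse = ", "))
    keep <- match(samples, rownames(v))
    v <- v[keep, , drop = FALSE]
    if (!is.null(lab)) lab <- lab[keep]
  }
  if (!is.null(genes)) {
    miss <- setdiff(genes, colnames(v))
    if (length(miss)) stop("unknown gene ids: ", paste(miss, collapse = ", "))
    v <- v[, genes, drop = FALSE]
  }
  gem(v, labels = lab)
}

#' Read a gene expression matrix from tab-separated text
#'
#' Expects a header row and a leading identifier column. Missing values
#' (`NA` or empty cells) are replaced by 0 at read time, before any
#' transformation. Gzip-compressed files are accepted.
#'
#' @param path path to a TSV (optionally .gz) file.
#' @param orientation `"genes_as_rows"` (the common public-dataset layout,
#'   default) or `"samples_as_rows"`. The matrix is stored samples x genes
#'   either way.
#' @return an unlabeled [gem].
#' @export
read_gem <- function(path, orientation = c("genes_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "")
  if (ncol(tab) < 2) stop("expected an identifier column plus data columns: ", path)
  ids <- tab[[1]]
  .check_unique(ids, if (orientation == "genes_as_rows") "gene id" else "sample id")
  cells <- as.matrix(tab[, -1, drop = FALSE])
  blank <- is.na(cells) | cells == "" | cells == "NA"
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num) & !blank, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value '%s' at row %d, column '%s' in %s",
                 cells[bad[1, 1], bad[1, 2]], bad[1, 1],
                 colnames(cells)[bad[1, 2]], path))
  }
  num[blank] <- 0
  dimnames(num) <- list(ids, colnames(cells))
  if (orientation == "genes_as_rows") num <- t(num)
  .check_unique(rownames(num), "sample id")
  gem(num)
}

#' Write a GEM as tab-separated text
#'
#' Inverse of [read_gem()]: first column `gene`, one column per sample
#' (`genes_as_rows`), or first column `sample` with one column per gene.
#'
#' @param g a [gem].
#' @param path output path.
#' @param orientation layout on disk; see [read_gem()].
#' @export
write_gem <- function(g, path, orientation = c("genes_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  stopifnot(is.gem(g))
  if (orientation == "genes_as_rows") {
    out <- data.frame(gene = colnames(g$values), t(g$values),
                      check.names = FALSE)
  } else {
    out <- data.frame(sample = rownames(g$values), g$values,
                      check.names = FALSE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach phenotype labels from a two-column table
#'
#' The label file is tab-separated `sample_id<TAB>label` with no header (a
#' header line `sample<TAB>label` is tolerated). Every sample in the GEM must
#' appear; labels for unknown samples are ignored with a warning.
#'
#' @param g a [gem].
#' @param labels_path path to the label TSV.
#' @return `g` with labels attached in sample order.
#' @export
attach_labels <- function(g, labels_path) {
  stopifnot(is.gem(g))
  tab <- utils::read.table(labels_path, header = FALSE, sep = "\t",
                           quote = "", colClasses = "character",
                           comment.char = "")
  if (ncol(tab) < 2) stop("label table needs two columns: sample id, label")
  if (identical(tolower(tab[1, 1]), "sample")) tab <- tab[-1, , drop = FALSE]
  map <- stats::setNames(tab[[2]], tab[[1]])
  miss <- setdiff(rownames(g$values), names(map))
  if (length(miss))
    stop("no label for samples: ", paste(miss, collapse = ", "))
  extra <- setdiff(names(map), rownames(g$values))
  if (length(extra))
    warning(sprintf("%d label(s) for unknown samples ignored", length(extra)))
  gem(g$values, labels = unname(map[rownames(g$values)]))
}

#' Write a per-sample label table
#'
#' @param g a labeled [gem].
#' @param path output path (TSV, `sample_id<TAB>label`, no header).
#' @export
write_labels <- function(g, path) {
  stopifnot(is.gem(g), !is.null(g$labels))
  utils::write.table(data.frame(rownames(g$values), g$labels), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Merge several GEMs on their shared genes
#'
#' Genes are restricted to the intersection across inputs, kept in the first
#' input's order; samples are concatenated and each input's samples receive
#' its assigned phenotype label. This mirrors assembling a two-state GEM from
#' per-phenotype source files.
#'
#' @param gems list of [gem] objects (at least 2).
#' @param label_per_gem character vector, one label per input GEM.
#' @return a labeled [gem].
#' @export
merge_gems <- function(gems, label_per_gem) {
  if (length(gems) < 2) stop("need at least two GEMs to merge")
  if (length(label_per_gem) != length(gems))
    stop("label_per_gem must have one label per input GEM")
  shared <- Reduce(intersect, lapply(gems, function(g) colnames(g$values)))
  if (!length(shared)) stop("no genes shared by all inputs")
  shared <- colnames(gems[[1]]$values)[colnames(gems[[1]]$values) %in% shared]
  vals <- do.call(rbind, lapply(gems, function(g) g$values[, shared, drop = FALSE]))
  labs <- rep(label_per_gem, vapply(gems, function(g) nrow(g$values), 1L))
  ids <- unlist(lapply(gems, function(g) rownames(g$values)), use.names = FALSE)
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  rownames(vals) <- ids
  gem(vals, labels = labs)
}

#' Read a GMT gene-set collection
#'
#' Standard MSigDB dialect: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within a line are removed, order preserved. Genes absent
#' from a particular GEM are dropped later, at subsetting time, not here.
#'
#' @param path path to a GMT file (optionally .gz).
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(stats::setNames(list(), character()))
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d field(s); need name, description, >=1 gene",
                   i, length(f)))
    nms[i] <- f[1]
    sets[[i]] <- unique(f[-(1:2)])
  }
  .check_unique(nms, "gene-set name")
  stats::setNames(sets, nms)
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of set descriptions
#'   (defaults to `"na"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
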