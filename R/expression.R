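# Sample x gene expression container and its normalization steps.

#' Construct an expression matrix
#'
#' Wraps a non-negative sample x gene matrix of FPKM-UQ-like values. The
#' log-normalized view `log10(1 + a)` is derived on demand via
#' [log_values()]; raw values are the single source of truth.
#'
#' @param raw numeric matrix, rows = samples, columns = genes, with dimnames.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(raw) {
  raw <- as.matrix(raw)
  if (is.null(rownames(raw)) || is.null(colnames(raw))) {
    stop_data("expression matrix needs sample rownames and gene colnames")
  }
  if (anyNA(raw) || any(!is.finite(raw))) {
    stop_data("expression values must be finite")
  }
  if (any(raw < 0)) stop_data("expression values must be non-negative")
  structure(list(raw = raw), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d samples x %d genes\n",
              nrow(x$raw), ncol(x$raw)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$raw)

#' Sample and gene identifiers
#' @param x an `expression_matrix`.
#' @return character vector.
#' @export
sample_ids <- function(x) rownames(x$raw)

#' @rdname sample_ids
#' @export
gene_ids <- function(x) colnames(x$raw)

#' Log-normalize expression values
#'
#' The `a -> log10(1 + a)` transform used throughout: it maps zero to zero,
#' is strictly increasing, and stops strongly expressed genes from dominating
#' a mean-squared-error loss.
#'
#' @param a non-negative numeric vector or matrix.
#' @return transformed values, same shape.
#' @export
log_normalize <- function(a) {
  if (any(a < 0, na.rm = TRUE)) stop_data("log_normalize: negative input")
  log10(1 + a)
}

#' Log-normalized view of an expression matrix
#' @param x an `expression_matrix`.
#' @return numeric matrix of `log10(1 + raw)` values.
#' @export
log_values <- function(x) log_normalize(x$raw)

#' Drop genes whose median raw expression is zero
#'
#' A gene not expressed in more than half the samples carries little signal
#' for regression and clutters downstream multiple testing, so it is removed.
#' The median is taken on raw (pre-log) values; the transform is applied
#' afterwards. Column order of the retained genes is preserved.
#'
#' @param mat an `expression_matrix`.
#' @return filtered `expression_matrix`.
#' @export
filter_genes_nonzero_median <- function(mat) {
  stopifnot(inherits(mat, "expression_matrix"))
  med <- apply(mat$raw, 2L, stats::median)
  keep <- med > 0
  if (!any(keep)) {
    warning("filter_genes_nonzero_median: no gene has nonzero median; ",
            "returning an empty gene set")
  }
  expression_matrix_allow_empty(mat$raw[, keep, drop = FALSE])
}

# internal: like expression_matrix() but tolerates zero genes
expression_matrix_allow_empty <- function(raw) {
  out <- structure(list(raw = as.matrix(raw)), class = "expression_matrix")
  out
}

#' Subset an expression matrix
#' @param x an `expression_matrix`.
#' @param samples,genes identifiers (or indices) to keep; `NULL` keeps all.
#' @return subsetted `expression_matrix`.
#' @export
subset_expression <- function(x, samples = NULL, genes = NULL) {
  raw <- x$raw
  if (!is.null(samples)) raw <- raw[samples, , drop = FALSE]
  if (!is.null(genes)) raw <- raw[, genes, drop = FALSE]
  expression_matrix_allow_empty(raw)
}
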