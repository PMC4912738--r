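#' Expression matrix container
#'
#' A light wrapper around a numeric genes-by-samples matrix carrying gene and
#' sample identifiers and a scale tag (`"raw"` measurement units or `"log"`
#' log-expression units). Unobserved cells are stored as `NA` and are never
#' used in arithmetic; the set of observed cells is carried separately by an
#' [observation_mask()].
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids character vector of row identifiers (defaults to rownames,
#'   or `g1, g2, ...` when absent). Must be unique.
#' @param sample_ids character vector of column identifiers (defaults to
#'   colnames, or `s1, s2, ...`). Must be unique.
#' @param scale `"raw"` or `"log"`.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, gene_ids = NULL, sample_ids = NULL,
                              scale = c("raw", "log")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop_("`values` must be a numeric matrix")
  m <- nrow(values); n <- ncol(values)
  if (m < 1L || n < 1L) stop_("matrix must have at least one row and one column")
  gene_ids <- gene_ids %||% rownames(values) %||% paste0("g", seq_len(m))
  sample_ids <- sample_ids %||% colnames(values) %||% paste0("s", seq_len(n))
  if (length(gene_ids) != m) stop_("gene_ids has length %d, expected %d", length(gene_ids), m)
  if (length(sample_ids) != n) stop_("sample_ids has length %d, expected %d", length(sample_ids), n)
  if (anyDuplicated(gene_ids)) stop_("duplicate gene id: %s", gene_ids[duplicated(gene_ids)][1L])
  if (anyDuplicated(sample_ids)) stop_("duplicate sample id: %s", sample_ids[duplicated(sample_ids)][1L])
  obs <- !is.na(values)
  if (any(!is.finite(values[obs])))
    stop_("non-finite observed values are not allowed")
  dimnames(values) <- list(as.character(gene_ids), as.character(sample_ids))
  structure(list(values = values, scale = scale), class = "expression_matrix")
}

#' @export
as.matrix.expression_matrix <- function(x, ...) x$values

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
dimnames.expression_matrix <- function(x) dimnames(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("expression_matrix: %d genes x %d samples (%s scale), %d unobserved cells\n",
              d[1L], d[2L], x$scale, sum(is.na(x$values))))
  invisible(x)
}

# Coerce expression_matrix | matrix to a plain numeric matrix.
values_of <- function(x) {
  if (inherits(x, "expression_matrix")) x$values
  else if (is.matrix(x) && is.numeric(x)) x
  else stop_("expected an expression_matrix or a numeric matrix")
}

#' Log-transform an expression matrix
#'
#' Expression measurements are heavily right-skewed; values are
#' log-transformed before low-rank prediction. Each observed value `v`
#' becomes `log(v + pseudocount, base)`; unobserved (`NA`) cells are left
#' untouched and the scale tag flips to `"log"`.
#'
#' @param x an [expression_matrix()] on the raw scale.
#' @param base logarithm base; default 2, the convention behind log2
#'   fold-changes in differential expression.
#' @param pseudocount added before taking logs so zero counts map to a finite
#'   value; default 1.
#' @return an `expression_matrix` on the log scale.
#' @seealso [inverse_log_transform()]
#' @export
log_transform <- function(x, base = 2, pseudocount = 1) {
  if (!inherits(x, "expression_matrix")) stop_("`x` must be an expression_matrix")
  if (x$scale != "raw") stop_("`x` is already on the log scale")
  v <- x$values
  obs <- which(!is.na(v))
  bad <- obs[v[obs] + pseudocount <= 0]
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(v))
    stop_("observed value %g at gene '%s', sample '%s' is <= -pseudocount (%g)",
          v[bad[1L]], rownames(v)[ij[1L]], colnames(v)[ij[2L]], pseudocount)
  }
  v[obs] <- log(v[obs] + pseudocount, base = base)
  expression_matrix(v, scale = "log")
}

#' Invert the log transformation
#'
#' Returns predictions to the measurement scale: each value `v` becomes
#' `base^v - pseudocount`. Overflow to non-finite values is an error.
#'
#' @inheritParams log_transform
#' @param x an [expression_matrix()] on the log scale.
#' @return an `expression_matrix` on the raw scale.
#' @export
inverse_log_transform <- function(x, base = 2, pseudocount = 1) {
  if (!inherits(x, "expression_matrix")) stop_("`x` must be an expression_matrix")
  if (x$scale != "log") stop_("`x` is not on the log scale")
  v <- x$values
  obs <- which(!is.na(v))
  v[obs] <- base^v[obs] - pseudocount
  if (any(!is.finite(v[obs]))) stop_("numeric overflow while inverting the log transform")
  expression_matrix(v, scale = "raw")
}
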