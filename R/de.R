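#' Moderated two-group differential expression test
#'
#' Per-gene two-sample moderated t-test on log-scale expression via
#' empirical-Bayes variance shrinkage (limma's `lmFit`/`eBayes`), with
#' Benjamini-Hochberg adjusted p-values and the difference of class means as
#' the log-fold-change. Genes can then be ranked by `|logFC|` or p-value.
#'
#' @param x an [expression_matrix()] or numeric matrix of log-scale values,
#'   genes in rows.
#' @param labels a two-level factor (or vector coercible to one) of length
#'   `ncol(x)`; each class needs at least 2 samples.
#' @return a data frame with one row per gene: `gene_id`, `logFC`
#'   (class 2 minus class 1), `t` (moderated statistic), `p_value`
#'   (two-sided), `adj_p_value` (BH).
#' @export
de_test <- function(x, labels) {
  v <- values_of(x)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop_("`labels` must have exactly two classes")
  if (length(labels) != ncol(v)) stop_("`labels` length must equal the number of samples")
  if (min(table(labels)) < 2L) stop_("each class needs at least 2 samples")
  design <- stats::model.matrix(~labels)
  fit <- limma::eBayes(limma::lmFit(v, design))
  p <- fit$p.value[, 2L]
  data.frame(
    gene_id = rownames(v) %||% paste0("g", seq_len(nrow(v))),
    logFC = unname(fit$coefficients[, 2L]),
    t = unname(fit$t[, 2L]),
    p_value = unname(p),
    adj_p_value = unname(bh_adjust(p)),
    row.names = NULL
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' The FDR-controlling step-up procedure used by [de_test()]: sorted
#' p-values are scaled by `m / rank` and a running minimum is taken from the
#' largest down. Delegates to [stats::p.adjust()].
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Impute unobserved cells by the gene's observed mean
#'
#' Builds the "checkpoint-only" comparator: the observed matrix with each
#' unobserved cell replaced by the mean of that gene's observed values, so
#' the differential-expression machinery can run on a complete matrix with
#' no low-rank prediction involved. Genes with no observed cell fall back to
#' the overall observed mean.
#'
#' @param x an [expression_matrix()] or numeric matrix.
#' @param mask an [observation_mask()] of the observed cells.
#' @return an object of the same type as `x`, fully observed.
#' @export
checkpoint_impute <- function(x, mask) {
  v <- values_of(x)
  if (!all(dim(v) == mask$shape)) stop_("matrix and mask dimensions disagree")
  obs <- array(NA_real_, dim = dim(v))
  obs[mask$idx] <- v[mask$idx]
  gene_means <- rowMeans(obs, na.rm = TRUE)
  gene_means[is.nan(gene_means)] <- mean(obs, na.rm = TRUE)
  fill <- matrix(gene_means, nrow(v), ncol(v))
  fill[mask$idx] <- v[mask$idx]
  dimnames(fill) <- dimnames(v)
  if (inherits(x, "expression_matrix")) expression_matrix(fill, scale = x$scale) else fill
}

#' Top-gene overlap between original and surrogate rankings
#'
#' Runs [de_test()] on the original matrix, the low-rank recovered matrix
#' and the checkpoint-only comparator, ranks genes by absolute
#' log-fold-change, and reports the fraction of the original top-`top_k`
#' genes recovered by each surrogate.
#'
#' @param original,recovered,checkpoint_only matrices of identical shape.
#' @param labels two-level class labels.
#' @param top_k number of top genes compared, `<= nrow(original)`.
#' @return named numeric vector with elements `recovered` and `checkpoint`.
#' @export
de_concordance <- function(original, recovered, checkpoint_only, labels, top_k) {
  m <- nrow(values_of(original))
  if (top_k > m) stop_("`top_k` exceeds the number of genes")
  tops <- lapply(list(original, recovered, checkpoint_only), function(x) {
    tab <- de_test(x, labels)
    tab$gene_id[order(-abs(tab$logFC))][seq_len(top_k)]
  })
  c(recovered = length(intersect(tops[[1L]], tops[[2L]])) / top_k,
    checkpoint = length(intersect(tops[[1L]], tops[[3L]])) / top_k)
}
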