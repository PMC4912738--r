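#' Recovery-error metrics
#'
#' Three relative errors quantify how well a recovered matrix `X` matches the
#' original `M`:
#' \describe{
#'   \item{Frobenius}{`||M - X||_F / ||M||_F`, an entrywise aggregate.}
#'   \item{Spectral}{`||M - X||_2 / ||M||_2` under the operator 2-norm
#'     (largest singular value).}
#'   \item{Omega}{`||P_Omega(X - M)||_F / ||P_Omega(M)||_F`, the mismatch on
#'     the observed cells only. It doubles as the solver's convergence
#'     criterion and, in practice, as an indicator of full-matrix recovery
#'     quality.}
#' }
#'
#' @param original,recovered numeric matrices (or [expression_matrix()]s) of
#'   the same shape.
#' @return a nonnegative number.
#' @name metrics
NULL

#' @rdname metrics
#' @export
frobenius_relative_error <- function(original, recovered) {
  M <- values_of(original); X <- values_of(recovered)
  check_same_shape(M, X)
  denom <- frob(M)
  if (denom == 0) stop_("`original` has zero Frobenius norm")
  frob(M - X) / denom
}

#' @rdname metrics
#' @export
spectral_relative_error <- function(original, recovered) {
  M <- values_of(original); X <- values_of(recovered)
  check_same_shape(M, X)
  denom <- spectral_norm(M)
  if (denom == 0) stop_("`original` has zero spectral norm")
  spectral_norm(M - X) / denom
}

#' @rdname metrics
#' @param mask an [observation_mask()] of the known cells.
#' @export
omega_error <- function(original, recovered, mask) {
  M <- values_of(original); X <- values_of(recovered)
  check_same_shape(M, X)
  if (!inherits(mask, "observation_mask")) stop_("`mask` must be an observation_mask")
  if (!all(dim(M) == mask$shape)) stop_("matrix and mask dimensions disagree")
  if (length(mask$idx) == 0L) stop_("empty mask")
  denom <- sqrt(sum(M[mask$idx]^2))
  if (denom == 0) stop_("observed part of `original` has zero norm")
  sqrt(sum((X[mask$idx] - M[mask$idx])^2)) / denom
}

#' Full error report for a completion
#'
#' Computes all three recovery metrics plus the observability in one call.
#'
#' @inheritParams omega_error
#' @return a one-row data frame with columns `frobenius_relative`,
#'   `spectral_relative`, `omega_relative`, `observability`.
#' @export
error_report <- function(original, recovered, mask) {
  data.frame(
    frobenius_relative = frobenius_relative_error(original, recovered),
    spectral_relative = spectral_relative_error(original, recovered),
    omega_relative = omega_error(original, recovered, mask),
    observability = observability(mask)
  )
}

check_same_shape <- function(M, X) {
  if (!all(dim(M) == dim(X)))
    stop_("matrices are %d x %d and %d x %d", nrow(M), ncol(M), nrow(X), ncol(X))
  if (any(!is.finite(M)) || any(!is.finite(X)))
    stop_("metrics require finite matrices")
  invisible(TRUE)
}
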