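#' Soft-thresholding (shrink) operator on singular values
#'
#' Given the singular value decomposition `x = sum_i sigma_i u_i v_i'`,
#' returns `sum_i max(sigma_i - tau, 0) u_i v_i'`. Every singular value is
#' reduced by `tau` and clipped at zero, so the operator lowers both the
#' nuclear norm and (weakly) the rank. It is a spectral function, hence
#' independent of the particular orthonormal basis returned for repeated
#' singular values.
#'
#' @param x a numeric matrix with finite entries.
#' @param tau nonnegative threshold.
#' @return a numeric matrix of the same shape.
#' @export
shrink <- function(x, tau) {
  x <- values_of(x)
  if (!all(is.finite(x))) stop_("`x` must be finite")
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0) stop_("`tau` must be a nonnegative scalar")
  shrink_full(x, tau)$x
}

# Full-SVD shrink; returns the matrix, retained singular values and rank.
shrink_full <- function(x, tau) {
  sv <- La.svd(x)
  d <- pmax(sv$d - tau, 0)
  keep <- which(d > 0)
  out <- if (length(keep) == 0L) {
    array(0, dim = dim(x))
  } else {
    sv$u[, keep, drop = FALSE] %*% (d[keep] * sv$vt[keep, , drop = FALSE])
  }
  list(x = out, d = d[keep], rank = length(keep))
}

# Top-s singular triplets by block subspace iteration with a deterministic
# Gaussian probe. Iterates until the singular values exceeding `tau` — the
# only ones the shrink operator retains — are stable to `tol` (relative);
# values at or below `tau` need only be located, not resolved. The spectral
# gap between the retained values and the bulk makes this converge in a few
# sweeps on SVT iterates.
svd_top <- function(x, s, tau = 0, tol = 1e-10, max_sweeps = 60L, oversample = 8L,
                    warm_start = NULL) {
  m <- nrow(x); n <- ncol(x)
  p <- min(m, n, s + oversample)
  G <- with_local_seed(760201L, matrix(stats::rnorm(n * p), n, p))
  Q <- qr.Q(qr(x %*% G))
  if (!is.null(warm_start) && nrow(warm_start) == m) {
    # seed the subspace with the previous iterate's left basis; the SVT
    # iterate moves little per step, so this cuts the sweep count sharply
    Q <- qr.Q(qr(cbind(warm_start[, seq_len(min(ncol(warm_start), p)), drop = FALSE],
                       Q)))[, seq_len(p), drop = FALSE]
  }
  d_old <- rep(Inf, p)
  for (sweep in seq_len(max_sweeps)) {
    sv <- La.svd(crossprod(Q, x))              # SVD of the p x n projection
    d <- sv$d
    watch <- d > tau
    if (!any(watch)) watch <- 1L               # track the top value at least
    if (max(abs(d[watch] - d_old[watch])) <= tol * max(d[1L], 1)) break
    d_old <- d
    Q <- qr.Q(qr(x %*% t(sv$vt)))              # re-orthonormalised left basis
  }
  sv <- La.svd(crossprod(Q, x))
  k <- min(s, p)
  U <- Q %*% sv$u
  list(u = U[, seq_len(k), drop = FALSE],
       d = sv$d[seq_len(k)],
       vt = sv$vt[seq_len(k), , drop = FALSE],
       basis = U)
}

# Shrink via truncated SVD with incremental rank probing: compute the top s
# singular triplets, and grow s until the smallest computed singular value
# falls at or below tau (so no retained value was missed). Falls back to the
# full decomposition when s approaches min(m, n).
shrink_truncated <- function(x, tau, rank_hint, warm_start = NULL, tol = 1e-10) {
  mn <- min(dim(x))
  if (rank_hint > mn %/% 4L) return(c(shrink_full(x, tau), list(basis = NULL)))
  s <- min(mn, max(rank_hint + 4L, 10L))
  repeat {
    sv <- svd_top(x, s, tau = tau, tol = tol, warm_start = warm_start)
    warm_start <- sv$basis
    if (sv$d[length(sv$d)] <= tau || length(sv$d) >= mn) break
    s <- s + max(5L, s %/% 2L)
    if (s >= mn %/% 2L) return(c(shrink_full(x, tau), list(basis = NULL)))
  }
  d <- pmax(sv$d - tau, 0)
  keep <- which(d > 0)
  out <- if (length(keep) == 0L) {
    array(0, dim = dim(x))
  } else {
    sv$u[, keep, drop = FALSE] %*% (d[keep] * sv$vt[keep, , drop = FALSE])
  }
  list(x = out, d = d[keep], rank = length(keep), basis = sv$basis)
}

#' Default singular-value threshold
#'
#' The standard heuristic `tau = 5 * sqrt(m * n)`. Large thresholds favour
#' low-rank iterates; too large a threshold over-shrinks and degrades
#' recovery.
#'
#' @param m,n dimensions of the matrix to be recovered.
#' @return the threshold.
#' @export
default_tau <- function(m, n) {
  if (m < 1 || n < 1) stop_("dimensions must be >= 1")
  5 * sqrt(as.double(m) * n)
}

#' Default gradient step size
#'
#' The standard heuristic `delta = 1.2 * m * n / |Omega|`: the sparser the
#' observations, the larger the step. Held constant across iterations.
#'
#' @param m,n dimensions of the matrix to be recovered.
#' @param observed_count number of observed cells, >= 1.
#' @return the step size.
#' @export
default_delta <- function(m, n, observed_count) {
  if (observed_count < 1) stop_("`observed_count` must be >= 1")
  total <- as.double(m) * n
  if (observed_count > total) stop_("`observed_count` exceeds m * n")
  1.2 * total / observed_count
}

#' Nuclear norm
#'
#' The sum of a matrix's singular values (Schatten 1-norm / trace norm): the
#' tightest convex relaxation of the rank, and the objective minimised by the
#' completion solver.
#'
#' @param x a numeric matrix with finite entries.
#' @return a nonnegative number.
#' @export
nuclear_norm <- function(x) {
  x <- values_of(x)
  if (!all(is.finite(x))) stop_("`x` must be finite")
  sum(svd(x, nu = 0, nv = 0)$d)
}

# Operator 2-norm (largest singular value). Power iteration on t(x) %*% x for
# large matrices, full SVD otherwise.
spectral_norm <- function(x, tol = 1e-10, max_iter = 1000L) {
  if (min(dim(x)) <= 400L) return(svd(x, nu = 0, nv = 0)$d[1L])
  v <- with_local_seed(760202L, stats::rnorm(ncol(x)))
  v <- v / sqrt(sum(v^2))
  s_old <- 0
  for (i in seq_len(max_iter)) {
    w <- crossprod(x, x %*% v)
    s <- sqrt(sqrt(sum(w^2)))
    v <- w / sqrt(sum(w^2))
    if (abs(s - s_old) <= tol * max(s, 1)) break
    s_old <- s
  }
  sqrt(sum((x %*% v)^2))
}

#' Complete an expression matrix by singular value thresholding
#'
#' Recovers a full genes-by-samples matrix from the observed checkpoint cells
#' by solving the nuclear-norm relaxation of rank minimisation with the SVT
#' iteration
#' \deqn{X^k = \mathrm{shrink}(Y^{k-1}, \tau), \quad
#'       Y^k = Y^{k-1} + \delta\, P_\Omega(M - X^k),}
#' starting from \eqn{Y^0 = 0}. The iteration stops when the omega error
#' \eqn{\|P_\Omega(X^k - M)\|_F / \|P_\Omega(M)\|_F} drops to `tolerance`
#' (converged), after `max_iter` iterations, or when the omega error exceeds
#' `divergence_factor` times its first-iteration value (flagged divergent).
#'
#' Matrices should normally be log-transformed first (see [log_transform()]);
#' the solver operates on whatever scale it is given.
#'
#' @param observed an [expression_matrix()] or numeric matrix holding the
#'   known values; cells outside the mask may be `NA`.
#' @param mask an [observation_mask()] of the known cells. If `NULL`, taken
#'   as the non-`NA` cells of `observed`.
#' @param tau singular-value threshold; default [default_tau()].
#' @param delta step size; default [default_delta()].
#' @param tolerance omega-error stopping threshold, default `1e-8`.
#' @param max_iter iteration cap, default 750.
#' @param divergence_factor declare divergence when the omega error exceeds
#'   this multiple of its first-iteration value; default 100.
#' @param restore_observed if `TRUE` (default) the observed cells of the
#'   returned matrix are overwritten with their measured values, since the
#'   constraint is equality on the mask; if `FALSE` the raw final iterate is
#'   returned.
#' @param svd_threshold use a full SVD when `min(m, n)` is at or below this
#'   size, and a truncated SVD with incremental rank probing above it.
#' @return an object of class `svt_completion` with components `recovered`
#'   (an [expression_matrix()] when the input was one, else a matrix),
#'   `omega_error_trace`, `iterations_run`, `converged`, `diverged`,
#'   `effective_rank`, and the parameters used.
#' @examples
#' truth <- generate_low_rank(60, 40, rank = 2, seed = 1)
#' mask <- sample_mask(60, 40, 0.6, seed = 2)
#' fit <- svt_complete(truth, mask)
#' frobenius_relative_error(truth, fitted(fit))
#' @export
svt_complete <- function(observed, mask = NULL, tau = NULL, delta = NULL,
                         tolerance = 1e-8, max_iter = 750L,
                         divergence_factor = 100,
                         restore_observed = TRUE, svd_threshold = 300L) {
  v <- values_of(observed)
  m <- nrow(v); n <- ncol(v)
  if (is.null(mask)) {
    mask <- observation_mask(which(!is.na(v)), m, n)
  }
  if (!inherits(mask, "observation_mask")) stop_("`mask` must be an observation_mask")
  if (!all(dim(v) == mask$shape)) stop_("matrix and mask dimensions disagree")
  if (length(mask$idx) == 0L) stop_("empty mask: nothing is observed")
  obs_vals <- v[mask$idx]
  if (any(!is.finite(obs_vals))) stop_("observed values must be finite on the mask")
  pm_norm <- sqrt(sum(obs_vals^2))
  if (pm_norm == 0) stop_("all observed values are zero: omega error is undefined")
  if (!is.numeric(tolerance) || tolerance <= 0) stop_("`tolerance` must be positive")
  if (max_iter < 1L) stop_("`max_iter` must be >= 1")
  if (divergence_factor <= 1) stop_("`divergence_factor` must exceed 1")
  tau <- tau %||% default_tau(m, n)
  delta <- delta %||% default_delta(m, n, length(mask$idx))
  if (tau <= 0 || delta <= 0) stop_("`tau` and `delta` must be positive")

  idx <- mask$idx
  Y <- array(0, dim = c(m, n))
  trace <- numeric(max_iter)
  converged <- FALSE
  diverged <- FALSE
  rank_hint <- 1L
  X <- NULL
  eff_rank <- 0L
  k <- 0L
  basis <- NULL
  last_omega <- 1
  for (k in seq_len(max_iter)) {
    # the truncated SVD need only be accurate well below the current omega
    # error; full precision is reserved for the end game near `tolerance`
    svd_tol <- max(1e-11, min(1e-4, 1e-3 * last_omega))
    sh <- if (min(m, n) <= svd_threshold) shrink_full(Y, tau)
          else shrink_truncated(Y, tau, rank_hint, warm_start = basis, tol = svd_tol)
    basis <- sh$basis
    X <- sh$x
    eff_rank <- sh$rank
    rank_hint <- max(sh$rank, 1L)
    resid <- obs_vals - X[idx]
    if (any(!is.finite(resid)))
      stop_("iterate diverged to non-finite values at iteration %d", k)
    omega <- sqrt(sum(resid^2)) / pm_norm
    trace[k] <- omega
    last_omega <- omega
    if (omega <= tolerance) { converged <- TRUE; break }
    if (k > 1L && omega > divergence_factor * trace[1L]) { diverged <- TRUE; break }
    Y[idx] <- Y[idx] + delta * resid
  }
  trace <- trace[seq_len(k)]
  omega_residuals <- obs_vals - X[idx]
  if (restore_observed) X[idx] <- obs_vals
  dimnames(X) <- dimnames(v)
  recovered <- if (inherits(observed, "expression_matrix"))
    expression_matrix(X, scale = observed$scale) else X

  structure(list(
    recovered = recovered,
    omega_error_trace = trace,
    iterations_run = k,
    converged = converged,
    diverged = diverged,
    effective_rank = eff_rank,
    omega_residuals = omega_residuals,
    mask = mask,
    params = list(tau = tau, delta = delta, tolerance = tolerance,
                  max_iter = as.integer(max_iter),
                  divergence_factor = divergence_factor,
                  restore_observed = restore_observed,
                  svd_threshold = as.integer(svd_threshold)),
    call = match.call()
  ), class = "svt_completion")
}

#' @export
print.svt_completion <- function(x, ...) {
  d <- dim(values_of(x$recovered))
  cat(sprintf("SVT matrix completion: %d x %d, O = %.3f\n",
              d[1L], d[2L], observability(x$mask)))
  cat(sprintf("  %d iterations, %s (final omega error %.3g), effective rank %d\n",
              x$iterations_run,
              if (x$converged) "converged"
              else if (x$diverged) "diverged" else "iteration cap reached",
              x$omega_error_trace[x$iterations_run], x$effective_rank))
  invisible(x)
}

#' @export
summary.svt_completion <- function(object, ...) {
  structure(list(fit = object), class = "summary.svt_completion")
}

#' @export
print.summary.svt_completion <- function(x, ...) {
  f <- x$fit
  print(f)
  p <- f$params
  cat(sprintf("  tau = %.6g, delta = %.6g, tolerance = %g, max_iter = %d\n",
              p$tau, p$delta, p$tolerance, p$max_iter))
  tr <- f$omega_error_trace
  cat(sprintf("  omega error: first %.3g, min %.3g, last %.3g\n",
              tr[1L], min(tr), tr[length(tr)]))
  cat(sprintf("  observed-cell residuals: RMS %.3g, max |.| %.3g\n",
              sqrt(mean(f$omega_residuals^2)), max(abs(f$omega_residuals))))
  invisible(x)
}

#' @export
fitted.svt_completion <- function(object, ...) {
  values_of(object$recovered)
}

#' Residuals of a completion fit on the observed cells
#'
#' Difference between the measured values and the final SVT iterate on the
#' mask (before any restoration of observed values); `NA` off the mask.
#' @param object an `svt_completion` fit.
#' @param ... unused.
#' @return a numeric matrix.
#' @export
residuals.svt_completion <- function(object, ...) {
  out <- array(NA_real_, dim = object$mask$shape)
  out[object$mask$idx] <- object$omega_residuals
  dimnames(out) <- dimnames(values_of(object$recovered))
  out
}

#' Plot the omega-error trace of an SVT fit
#' @param x an `svt_completion` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.svt_completion <- function(x, ...) {
  graphics::plot(seq_along(x$omega_error_trace), x$omega_error_trace,
                 type = "l", log = "y", xlab = "iteration",
                 ylab = "omega error", ...)
  graphics::abline(h = x$params$tolerance, lty = 3)
  invisible(x)
}
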