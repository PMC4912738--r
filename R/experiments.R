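# End-to-end simulation studies: noise robustness, tau/delta sweep,
# observability sweep, and differential-expression concordance.

#' Noise-robustness benchmark
#'
#' For every (noise ratio, observability) cell: generate a rank-`rank`
#' Gaussian-factor truth, sample a uniform mask, add white Gaussian noise on
#' the observed cells, run the SVT solver capped at `iterations`, and record
#' the Frobenius relative error of the recovered matrix against the clean
#' truth. Each cell is replicated with fresh seeds and the mean and standard
#' deviation reported.
#'
#' @param m,n,rank truth dimensions and rank.
#' @param ratios noise deviation ratios to test.
#' @param observabilities observed fractions to test.
#' @param iterations SVT iteration cap per run.
#' @param replicates runs per cell.
#' @param seed base integer seed; per-run seeds are derived from it.
#' @param svd_threshold passed to [svt_complete()].
#' @return a data frame with one row per cell: `ratio`, `observability`,
#'   `iterations`, `relative_error_mean`, `relative_error_sd`, `replicates`,
#'   `failed` (runs that errored, excluded from the mean), `seeds`.
#' @export
noise_benchmark <- function(m = 500, n = 500, rank = 10,
                            ratios = c(0.003, 0.03, 0.3),
                            observabilities = c(0.5, 0.1),
                            iterations = 100, replicates = 5, seed = 1,
                            svd_threshold = 300L) {
  grid <- expand.grid(ratio = ratios, observability = observabilities,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  run_id <- 0L
  for (g in seq_len(nrow(grid))) {
    errs <- rep(NA_real_, replicates)
    seeds <- integer(replicates)
    for (r in seq_len(replicates)) {
      run_id <- run_id + 1L
      s <- (seed + 7919L * run_id) %% .Machine$integer.max
      seeds[r] <- s
      errs[r] <- tryCatch({
        truth <- generate_low_rank(m, n, rank, seed = s)
        mask <- sample_mask(m, n, grid$observability[g], seed = s + 1L)
        noisy <- add_noise(truth, mask, grid$ratio[g], seed = s + 2L)
        # evaluate the raw low-rank iterate: restoring the noisy measured
        # values onto the observed cells would floor the error at
        # ratio * sqrt(O), whereas the low-rank estimate averages the noise
        fit <- svt_complete(noisy, mask, max_iter = iterations,
                            restore_observed = FALSE,
                            svd_threshold = svd_threshold)
        frobenius_relative_error(truth, fitted(fit))
      }, error = function(e) NA_real_)
    }
    ok <- !is.na(errs)
    rows[[g]] <- data.frame(
      ratio = grid$ratio[g], observability = grid$observability[g],
      iterations = iterations,
      relative_error_mean = if (any(ok)) mean(errs[ok]) else NA_real_,
      relative_error_sd = if (sum(ok) > 1L) stats::sd(errs[ok]) else NA_real_,
      replicates = sum(ok), failed = sum(!ok),
      seeds = paste(seeds, collapse = ",")
    )
  }
  do.call(rbind, rows)
}

#' Threshold / step-size sweep
#'
#' Relative recovery error over a grid of (`tau`, `delta`) values on a single
#' fixed low-rank truth, mask and noise realisation — the classic map showing
#' that the `5*sqrt(mn)` and `1.2*mn/|Omega|` heuristics sit near the
#' well-performing region, while extreme thresholds over-shrink.
#'
#' @inheritParams noise_benchmark
#' @param observability observed fraction for the single fixed mask.
#' @param tau_grid,delta_grid parameter values to cross.
#' @param ratio noise deviation ratio of the fixed realisation (0 = clean).
#' @return a data frame with columns `tau`, `delta`, `relative_error`
#'   (`NA` where the solver failed).
#' @export
parameter_sweep <- function(m = 150, n = 150, rank = 10, observability = 0.5,
                            tau_grid, delta_grid, iterations = 100,
                            ratio = 0, seed = 1, svd_threshold = 300L) {
  if (!length(tau_grid) || !length(delta_grid)) stop_("parameter grids must be nonempty")
  truth <- generate_low_rank(m, n, rank, seed = seed)
  mask <- sample_mask(m, n, observability, seed = seed + 1L)
  noisy <- add_noise(truth, mask, ratio, seed = seed + 2L)
  grid <- expand.grid(tau = tau_grid, delta = delta_grid, KEEP.OUT.ATTRS = FALSE)
  grid$relative_error <- vapply(seq_len(nrow(grid)), function(i) {
    tryCatch({
      fit <- svt_complete(noisy, mask, tau = grid$tau[i], delta = grid$delta[i],
                          max_iter = iterations, svd_threshold = svd_threshold)
      frobenius_relative_error(truth, fitted(fit))
    }, error = function(e) NA_real_)
  }, numeric(1))
  grid
}

#' Observability sweep on a fixed matrix
#'
#' For each target observability, repeatedly masks the supplied matrix at
#' fresh random checkpoint locations, completes it, and averages the three
#' recovery metrics over the runs. Divergent runs are excluded from the means
#' and counted.
#'
#' @param x the complete matrix to mask and recover.
#' @param observabilities grid of observed fractions; default 0.1 to 0.9.
#' @param runs_per_point masks per observability; default 10.
#' @param seed base integer seed.
#' @param max_iter,svd_threshold passed to [svt_complete()].
#' @return a data frame with one row per observability: mean `frobenius`,
#'   `spectral`, `omega` errors, `runs` used and `diverged` count.
#' @export
observability_sweep <- function(x, observabilities = seq(0.1, 0.9, by = 0.1),
                                runs_per_point = 10, seed = 1,
                                max_iter = 750L, svd_threshold = 300L) {
  if (any(observabilities <= 0 | observabilities >= 1))
    stop_("observabilities must lie in (0, 1)")
  v <- values_of(x)
  rows <- lapply(seq_along(observabilities), function(oi) {
    O <- observabilities[oi]
    res <- matrix(NA_real_, runs_per_point, 3L)
    div <- 0L
    for (r in seq_len(runs_per_point)) {
      s <- (seed + 7919L * (oi * 1000L + r)) %% .Machine$integer.max
      mask <- sample_mask(nrow(v), ncol(v), O, seed = s)
      fit <- tryCatch(
        svt_complete(v, mask, max_iter = max_iter, svd_threshold = svd_threshold),
        error = function(e) NULL)
      if (is.null(fit) || fit$diverged) { div <- div + 1L; next }
      res[r, ] <- c(frobenius_relative_error(v, fitted(fit)),
                    spectral_relative_error(v, fitted(fit)),
                    utils::tail(fit$omega_error_trace, 1L))
    }
    ok <- stats::complete.cases(res)
    data.frame(observability = O,
               frobenius = mean(res[ok, 1L]), spectral = mean(res[ok, 2L]),
               omega = mean(res[ok, 3L]), runs = sum(ok), diverged = div)
  })
  do.call(rbind, rows)
}

#' Omega-error indicator study
#'
#' Runs the solver across a grid of observabilities and noise ratios on
#' fresh synthetic low-rank matrices and records, per run, the final omega
#' error and the full-matrix Frobenius relative error. A positive rank
#' correlation between the two is what licenses using the omega error — the
#' only error observable in practice — as an indicator of recovery quality.
#'
#' @inheritParams noise_benchmark
#' @param observabilities,ratios grids crossed to produce one run per pair.
#' @param iterations SVT iteration cap per run.
#' @return a data frame with one row per run: `observability`, `ratio`,
#'   `omega`, `frobenius`, `converged`.
#' @export
omega_indicator_study <- function(m = 100, n = 80, rank = 5,
                                  observabilities = seq(0.1, 0.9, by = 0.1),
                                  ratios = c(0, 0.03, 0.3),
                                  iterations = 100, seed = 1,
                                  svd_threshold = 300L) {
  grid <- expand.grid(observability = observabilities, ratio = ratios,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    s <- (seed + 104729L * i) %% .Machine$integer.max
    truth <- generate_low_rank(m, n, rank, seed = s)
    mask <- sample_mask(m, n, grid$observability[i], seed = s + 1L)
    noisy <- add_noise(truth, mask, grid$ratio[i], seed = s + 2L)
    fit <- tryCatch(
      svt_complete(noisy, mask, max_iter = iterations, restore_observed = FALSE,
                   svd_threshold = svd_threshold),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    data.frame(observability = grid$observability[i], ratio = grid$ratio[i],
               omega = utils::tail(fit$omega_error_trace, 1L),
               frobenius = frobenius_relative_error(truth, fitted(fit)),
               converged = fit$converged)
  })
  do.call(rbind, rows)
}

#' Differential-expression concordance benchmark
#'
#' The end-to-end surrogate-data experiment: generate two-class data with
#' planted differential genes, mask it, recover the full matrix by SVT, and
#' compare the top-`top_k` gene ranking (by |logFC|) of (a) the low-rank
#' recovered matrix and (b) the checkpoint-only mean-imputed matrix against
#' the ranking from the complete original. Repeated over seeds.
#'
#' @param m number of genes.
#' @param n_per_class samples per class.
#' @param n_de,effect_size,noise_sd planted-signal parameters, see
#'   [generate_two_class()].
#' @param observability observed fraction.
#' @param top_k ranking depth compared.
#' @param seeds integer vector, one run per seed.
#' @param max_iter SVT iteration cap.
#' @return a data frame with one row per seed: `seed`, `overlap_recovered`,
#'   `overlap_checkpoint`.
#' @export
de_concordance_benchmark <- function(m = 2000, n_per_class = 40, n_de = 100,
                                     effect_size = 2, noise_sd = 1,
                                     observability = 0.6, top_k = 100,
                                     seeds = 1:10, max_iter = 750L) {
  rows <- lapply(seeds, function(s) {
    sim <- generate_two_class(m, n_per_class, n_de, effect_size, noise_sd, seed = s)
    mask <- sample_mask(m, 2L * n_per_class, observability, seed = s + 500000L)
    fit <- svt_complete(sim$matrix$values, mask, max_iter = max_iter)
    cp <- checkpoint_impute(sim$matrix$values, mask)
    ov <- de_concordance(sim$matrix$values, fitted(fit), cp, sim$labels, top_k)
    data.frame(seed = s, overlap_recovered = ov[["recovered"]],
               overlap_checkpoint = ov[["checkpoint"]])
  })
  do.call(rbind, rows)
}
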