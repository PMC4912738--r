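test_that("shrink reproduces the closed-form action on singular values", {
  # diagonal matrix: SVD is explicit
  x <- diag(c(5, 3, 1))
  expect_equal(shrink(x, 2), diag(c(3, 1, 0)), tolerance = 1e-12)
  expect_equal(shrink(x, 0), x, tolerance = 1e-12)
  # sigma exactly equal to tau shrinks to zero
  expect_equal(shrink(diag(c(4, 2)), 2), diag(c(2, 0)), tolerance = 1e-12)
  expect_error(shrink(matrix(c(1, NA), 1, 2), 1), "finite")
  expect_error(shrink(diag(2), -1), "tau")
})

test_that("shrink matches an independent full-SVD oracle on random matrices", {
  withr::with_seed(101, {
    for (rep in 1:10) {
      x <- matrix(rnorm(400), 20, 20)
      d_ref <- svd(x)$d  # independent oracle
      for (tau in c(0, d_ref[1] / 2, d_ref[1])) {
        got <- svd(shrink(x, tau))$d
        expect_equal(got, pmax(d_ref - tau, 0), tolerance = 1e-9)
        expect_equal(nuclear_norm(shrink(x, tau)), sum(pmax(d_ref - tau, 0)),
                     tolerance = 1e-9)
      }
    }
  })
})

test_that("shrink never increases singular values; rank decreases with tau", {
  x <- withr::with_seed(7, matrix(rnorm(15 * 12), 15, 12))
  d0 <- svd(x)$d
  taus <- c(0.1, 0.5, 1, 2, 4)
  ranks <- vapply(taus, function(tau) {
    d <- svd(shrink(x, tau))$d
    expect_true(all(d <= d0 + 1e-10))
    sum(d > 1e-10)
  }, numeric(1))
  expect_true(all(diff(ranks) <= 0))
})

test_that("parameter heuristics follow the standard relations", {
  expect_equal(default_tau(150, 150), 750)
  expect_equal(default_tau(2000, 2000), 10000)
  expect_equal(default_tau(1, 1), 5)
  expect_equal(default_delta(10, 10, 100), 1.2)
  expect_equal(default_delta(100, 100, 5000), 2.4)
  expect_equal(default_delta(100, 100, 1000), 12)
  expect_error(default_delta(10, 10, 0), "observed_count")
})

test_that("nuclear norm sums singular values and is orthogonally invariant", {
  expect_equal(nuclear_norm(matrix(0, 4, 4)), 0)
  expect_equal(nuclear_norm(diag(c(5, 3, 1))), 9)
  withr::with_seed(5, {
    x <- matrix(rnorm(100), 10, 10)
    Q <- qr.Q(qr(matrix(rnorm(100), 10, 10)))
    R <- qr.Q(qr(matrix(rnorm(100), 10, 10)))
    expect_equal(nuclear_norm(Q %*% x %*% R), nuclear_norm(x), tolerance = 1e-9)
    expect_equal(nuclear_norm(x), sum(svd(x)$d), tolerance = 1e-10)
  })
})

test_that("noiseless low-rank matrices are recovered to high accuracy", {
  truth <- generate_low_rank(80, 60, rank = 2, seed = 1)
  mask <- sample_mask(80, 60, 0.6, seed = 2)
  fit <- svt_complete(truth, mask)
  expect_true(fit$converged)
  expect_lte(utils::tail(fit$omega_error_trace, 1), 1e-8)
  expect_lte(frobenius_relative_error(truth, fitted(fit)), 1e-3)
  expect_equal(fit$effective_rank, 2)
  expect_equal(length(fit$omega_error_trace), fit$iterations_run)
})

test_that("a fully observed matrix converges and is reproduced on the mask", {
  x <- tiny_matrix(20, 10, seed = 8)
  full <- observation_mask(seq_len(200), 20, 10)
  fit <- svt_complete(x, full, max_iter = 750)
  expect_true(fit$converged)
  expect_equal(fitted(fit)[full$idx], x$values[full$idx], ignore_attr = TRUE)
})

test_that("restore_observed controls whether mask cells equal the input", {
  truth <- generate_low_rank(40, 30, 2, seed = 3)
  mask <- sample_mask(40, 30, 0.5, seed = 4)
  noisy <- add_noise(truth, mask, 0.1, seed = 5)
  kept <- svt_complete(noisy, mask, max_iter = 50)
  raw <- svt_complete(noisy, mask, max_iter = 50, restore_observed = FALSE)
  expect_equal(fitted(kept)[mask$idx], as.matrix(noisy)[mask$idx])
  expect_false(isTRUE(all.equal(fitted(raw)[mask$idx],
                                as.matrix(noisy)[mask$idx])))
})

test_that("identical inputs give identical traces; NAs define the mask", {
  truth <- generate_low_rank(50, 40, 3, seed = 6)
  mask <- sample_mask(50, 40, 0.5, seed = 7)
  f1 <- svt_complete(truth, mask, max_iter = 40)
  f2 <- svt_complete(truth, mask, max_iter = 40)
  expect_identical(f1$omega_error_trace, f2$omega_error_trace)
  # equivalent call with NA-coded unobserved cells
  v <- as.matrix(truth)
  v[mask_complement(mask)$idx] <- NA
  f3 <- svt_complete(v, max_iter = 40)
  expect_identical(f3$omega_error_trace, f1$omega_error_trace)
})

test_that("truncated and full SVD backends agree on small problems", {
  truth <- generate_low_rank(10, 10, 2, seed = 11)
  mask <- sample_mask(10, 10, 0.8, seed = 12)
  f_full <- svt_complete(truth, mask, max_iter = 60, svd_threshold = 300)
  f_trunc <- svt_complete(truth, mask, max_iter = 60, svd_threshold = 0)
  expect_equal(f_trunc$omega_error_trace, f_full$omega_error_trace,
               tolerance = 1e-8)
  expect_true(max(abs(fitted(f_trunc) - fitted(f_full))) < 1e-8)
})

test_that("solver input validation fails loudly", {
  x <- matrix(1:12, 3, 4)
  expect_error(svt_complete(x, observation_mask(integer(0), 3, 4)), "empty mask")
  expect_error(svt_complete(matrix(0, 3, 4), observation_mask(1:12, 3, 4)),
               "zero")
  expect_error(svt_complete(x, observation_mask(1:6, 2, 3)), "disagree")
  expect_error(svt_complete(x, observation_mask(1:12, 3, 4), max_iter = 0),
               "max_iter")
})

test_that("divergence is detected and flagged rather than silently returned", {
  truth <- generate_low_rank(40, 30, 3, seed = 13)
  mask <- sample_mask(40, 30, 0.3, seed = 14)
  # an absurd step size makes the residual blow up
  fit <- tryCatch(
    svt_complete(truth, mask, delta = 500, max_iter = 200, divergence_factor = 10),
    error = function(e) e)
  if (inherits(fit, "error")) {
    expect_match(conditionMessage(fit), "diverged")
  } else {
    expect_false(fit$converged)
    expect_true(fit$diverged)
    expect_lt(fit$iterations_run, 200)
  }
})

test_that("completion methods print, plot and summarise without error", {
  truth <- generate_low_rank(30, 20, 2, seed = 15)
  mask <- sample_mask(30, 20, 0.7, seed = 16)
  fit <- svt_complete(truth, mask)
  expect_output(print(fit), "SVT matrix completion")
  expect_output(print(summary(fit)), "tau")
  r <- residuals(fit)
  expect_equal(dim(r), c(30L, 20L))
  expect_true(all(is.na(r[mask_complement(mask)$idx])))
  # residual norm on the mask reproduces the final omega error
  expect_equal(sqrt(sum(r[mask$idx]^2)) / sqrt(sum(as.matrix(truth)[mask$idx]^2)),
               utils::tail(fit$omega_error_trace, 1))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
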