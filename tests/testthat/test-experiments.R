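test_that("noise benchmark aggregates replicates reproducibly", {
  res <- noise_benchmark(m = 80, n = 60, rank = 3, ratios = c(0, 0.05),
                         observabilities = 0.5, iterations = 60,
                         replicates = 2, seed = 4)
  expect_equal(nrow(res), 2L)
  expect_true(all(res$replicates == 2))
  expect_true(all(res$relative_error_sd >= 0))
  # noiseless cell sits well below the noisy cell
  expect_lt(res$relative_error_mean[res$ratio == 0],
            res$relative_error_mean[res$ratio == 0.05])
  res2 <- noise_benchmark(m = 80, n = 60, rank = 3, ratios = c(0, 0.05),
                          observabilities = 0.5, iterations = 60,
                          replicates = 2, seed = 4)
  expect_identical(res, res2)
})

test_that("the default tau/delta cell is competitive in a parameter sweep", {
  tau0 <- default_tau(100, 80)
  delta0 <- default_delta(100, 80, round(0.5 * 100 * 80))
  res <- parameter_sweep(m = 100, n = 80, rank = 5, observability = 0.5,
                         tau_grid = c(tau0 / 5, tau0, 100 * tau0),
                         delta_grid = c(delta0 / 2, delta0),
                         iterations = 100, seed = 2)
  expect_equal(nrow(res), 6L)
  default_cell <- res$relative_error[res$tau == tau0 & res$delta == delta0]
  best <- min(res$relative_error, na.rm = TRUE)
  expect_lte(default_cell, 10 * best)
  # an extreme threshold over-shrinks and performs worse than the default
  huge_tau <- res$relative_error[res$tau == 100 * tau0 & res$delta == delta0]
  expect_gt(huge_tau, default_cell)
  # duplicate grid points give identical errors (determinism)
  dup <- parameter_sweep(m = 40, n = 30, rank = 2, observability = 0.6,
                         tau_grid = rep(default_tau(40, 30), 2),
                         delta_grid = 1.5, iterations = 50, seed = 3)
  expect_equal(dup$relative_error[1], dup$relative_error[2])
})

test_that("recovery error falls as observability rises on low-rank input", {
  x <- generate_low_rank(120, 60, 4, seed = 5)
  res <- observability_sweep(x, observabilities = c(0.2, 0.5, 0.9),
                             runs_per_point = 3, seed = 6, max_iter = 300)
  expect_equal(nrow(res), 3L)
  expect_lt(res$frobenius[res$observability == 0.9],
            res$frobenius[res$observability == 0.2])
  expect_lte(res$frobenius[res$observability == 0.9], 1e-3)
})

test_that("omega error tracks the unobservable full-matrix error", {
  res <- omega_indicator_study(m = 80, n = 50, rank = 4,
                               observabilities = c(0.2, 0.5, 0.8),
                               ratios = c(0, 0.1), iterations = 80, seed = 7)
  expect_gte(nrow(res), 5L)
  expect_gt(cor(res$omega, res$frobenius, method = "spearman"), 0)
})

test_that("de_test returns moderated statistics with sensible structure", {
  sim <- generate_two_class(m = 200, n_per_class = 10, n_de = 20,
                            effect_size = 5, noise_sd = 1, seed = 8)
  de <- de_test(sim$matrix, sim$labels)
  expect_named(de, c("gene_id", "logFC", "t", "p_value", "adj_p_value"))
  # strong planted effects occupy the top ranks
  top <- de$gene_id[order(de$p_value)][1:20]
  expect_setequal(top, sim$de_genes)
  expect_true(all(de$adj_p_value >= de$p_value - 1e-15))
  # identical classes (duplicated samples) have zero fold-change
  v <- as.matrix(sim$matrix)[, c(1:10, 1:10)]
  colnames(v) <- paste0("s", 1:20)
  de0 <- de_test(v, rep(c("a", "b"), each = 10))
  expect_equal(max(abs(de0$logFC)), 0)
  expect_error(de_test(v, rep("a", 20)), "two classes")
  expect_error(de_test(v[, 1:11], c(rep("a", 10), "b")), "at least 2")
})

test_that("BH adjustment follows the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # hand-computed: sorted p * m / rank, running min from the top
  p <- c(0.005, 0.04, 0.03, 0.8)
  expect_equal(bh_adjust(p), c(0.02, 0.16 / 3, 0.16 / 3, 0.8))
})

test_that("checkpoint imputation fills unobserved cells with gene means", {
  v <- matrix(c(1, 2, 3, 5, NA, 7, NA, 10, 11), 3, 3)
  mask <- observation_mask(which(!is.na(v)), 3, 3)
  out <- checkpoint_impute(v, mask)
  expect_equal(out[2, 2], mean(c(2, 10)))
  expect_equal(out[1, 3], mean(c(1, 5)))
  expect_equal(out[mask$idx], v[mask$idx])
})

test_that("de_concordance is 1 for a perfect surrogate and ~k/m for random ones", {
  sim <- generate_two_class(m = 150, n_per_class = 8, n_de = 15,
                            effect_size = 3, noise_sd = 1, seed = 9)
  v <- as.matrix(sim$matrix)
  ov <- de_concordance(v, v, v, sim$labels, top_k = 15)
  expect_equal(unname(ov), c(1, 1))
  expect_error(de_concordance(v, v, v, sim$labels, top_k = 151), "top_k")
  # combinatorial baseline: two independent rankings of m genes share
  # k^2/m expected entries in their top-k (k/m of the top-k set)
  m <- 400; k <- 40; B <- 200
  overlaps <- withr::with_seed(10, replicate(B, {
    length(intersect(sample(m, k), sample(m, k))) / k
  }))
  expect_equal(mean(overlaps), k / m, tolerance = 0.25)
})

test_that("low-rank recovery preserves the DE ranking at least as well as
           checkpoint-only imputation", {
  dc <- de_concordance_benchmark(m = 2000, n_per_class = 40, n_de = 100,
                                 effect_size = 2, noise_sd = 1,
                                 observability = 0.6, top_k = 100,
                                 seeds = 1:3)
  expect_true(all(dc$overlap_recovered >= dc$overlap_checkpoint))
  expect_true(all(dc$overlap_recovered >= 0.95))
})
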