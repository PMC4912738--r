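#' Generate a random low-rank matrix
#'
#' Draws factor matrices `A` (`m x rank`) and `B` (`n x rank`) with
#' independent standard-normal entries scaled by `factor_scale` and returns
#' `A %*% t(B)`: a matrix of numerical rank exactly `rank` (almost surely).
#' These Gaussian-factor matrices are the inputs of the solver's parameter
#' and noise-robustness studies.
#'
#' @param m,n dimensions.
#' @param rank target rank, `1 <= rank <= min(m, n)`.
#' @param factor_scale standard deviation of the factor entries; default 1.
#' @param seed integer seed; the draw is fully reproducible.
#' @return an [expression_matrix()] on the log scale (values are signed,
#'   emulating centred log-expression).
#' @export
generate_low_rank <- function(m, n, rank, factor_scale = 1, seed) {
  if (rank < 1 || rank > min(m, n)) stop_("`rank` must lie in [1, min(m, n)]")
  v <- with_local_seed(seed, {
    A <- matrix(stats::rnorm(m * rank, sd = factor_scale), m, rank)
    B <- matrix(stats::rnorm(n * rank, sd = factor_scale), n, rank)
    A %*% t(B)
  })
  expression_matrix(v, scale = "log")
}

#' Add white Gaussian noise to the observed cells
#'
#' Perturbs each observed checkpoint value as `x' = x + e` with
#' `e ~ N(0, (ratio * sigma_x)^2)`, where `ratio` is the noise deviation
#' ratio `sigma_e / sigma_x` and `sigma_x` is the standard deviation of the
#' signal. Cells outside the mask are untouched, mirroring the fact that
#' measurement noise only afflicts cells that were measured.
#'
#' @param x an [expression_matrix()] or numeric matrix.
#' @param mask an [observation_mask()]; noise is applied on these cells only.
#' @param ratio noise deviation ratio, >= 0.
#' @param seed integer seed.
#' @param sigma_scope `"observed"` (default) estimates `sigma_x` from the
#'   cells in the mask — the quantity available in practice — or `"full"`
#'   from the whole matrix.
#' @return an object of the same type as `x`.
#' @export
add_noise <- function(x, mask, ratio, seed, sigma_scope = c("observed", "full")) {
  sigma_scope <- match.arg(sigma_scope)
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio < 0)
    stop_("`ratio` must be a nonnegative scalar")
  v <- values_of(x)
  if (!all(dim(v) == mask$shape)) stop_("matrix and mask dimensions disagree")
  if (ratio > 0) {
    sigma_x <- if (sigma_scope == "observed") stats::sd(v[mask$idx]) else stats::sd(v)
    eps <- with_local_seed(seed,
      stats::rnorm(length(mask$idx), mean = 0, sd = ratio * sigma_x))
    v[mask$idx] <- v[mask$idx] + eps
  }
  if (inherits(x, "expression_matrix")) expression_matrix(v, scale = x$scale) else v
}

#' Generate two-class expression data with planted differential genes
#'
#' A synthetic stand-in for a case/control profiling experiment on the log
#' scale: each gene gets a baseline level drawn from
#' `N(baseline_mean, baseline_sd^2)`, the first `n_de` genes get an
#' additional mean shift of `effect_size` in class 2, and i.i.d. Gaussian
#' noise with standard deviation `noise_sd` is added to every cell.
#'
#' @param m number of genes.
#' @param n_per_class samples per class.
#' @param n_de number of planted differentially expressed genes, `<= m`.
#' @param effect_size class-2 mean shift for the planted genes (log2 units).
#' @param noise_sd per-cell noise standard deviation.
#' @param seed integer seed.
#' @param baseline_mean,baseline_sd distribution of per-gene baseline
#'   log2-expression; defaults 7 and 2, typical of normalised microarray
#'   intensities.
#' @return a list with `matrix` (an [expression_matrix()] on the log scale),
#'   `labels` (factor with levels `class1`, `class2`) and `de_genes`
#'   (character vector of planted gene ids).
#' @export
generate_two_class <- function(m, n_per_class, n_de, effect_size, noise_sd,
                               seed, baseline_mean = 7, baseline_sd = 2) {
  if (n_de > m) stop_("`n_de` cannot exceed the number of genes")
  if (m < 1 || n_per_class < 1 || n_de < 0) stop_("invalid sizes")
  n <- 2L * n_per_class
  v <- with_local_seed(seed, {
    baseline <- stats::rnorm(m, baseline_mean, baseline_sd)
    v <- matrix(baseline, m, n) +
      matrix(stats::rnorm(m * n, sd = noise_sd), m, n)
    if (n_de > 0)
      v[seq_len(n_de), seq(n_per_class + 1L, n)] <-
        v[seq_len(n_de), seq(n_per_class + 1L, n)] + effect_size
    v
  })
  labels <- factor(rep(c("class1", "class2"), each = n_per_class))
  x <- expression_matrix(v, scale = "log")
  list(matrix = x,
       labels = labels,
       de_genes = rownames(x$values)[seq_len(n_de)])
}
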