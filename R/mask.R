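#' Observation mask
#'
#' Represents the index set of known ("checkpoint") cells of an
#' `m x n` matrix, together with the orthogonal projection onto those cells.
#' Entries are stored as sorted 1-based column-major linear indices.
#'
#' @param entries either a two-column integer matrix of (row, column) pairs
#'   or an integer vector of column-major linear indices.
#' @param m,n matrix dimensions.
#' @param seed optional integer recorded for provenance when the mask was
#'   randomly sampled.
#' @return an object of class `observation_mask`.
#' @export
observation_mask <- function(entries, m, n, seed = NULL) {
  m <- as.integer(m); n <- as.integer(n)
  if (m < 1L || n < 1L) stop_("mask dimensions must be positive")
  if (is.matrix(entries)) {
    if (ncol(entries) != 2L) stop_("`entries` matrix must have two columns (row, col)")
    if (nrow(entries) && (any(entries[, 1L] < 1L | entries[, 1L] > m) ||
                          any(entries[, 2L] < 1L | entries[, 2L] > n)))
      stop_("mask entry out of range for a %d x %d matrix", m, n)
    idx <- (as.integer(entries[, 2L]) - 1L) * m + as.integer(entries[, 1L])
  } else {
    idx <- as.integer(entries)
    if (length(idx) && (any(idx < 1L) || any(idx > m * n)))
      stop_("mask index out of range for a %d x %d matrix", m, n)
  }
  idx <- sort.int(idx)
  if (anyDuplicated(idx)) stop_("duplicate mask entries")
  structure(list(shape = c(m, n), idx = idx, seed = seed),
            class = "observation_mask")
}

#' @export
print.observation_mask <- function(x, ...) {
  cat(sprintf("observation_mask: %d of %d cells observed (O = %.4g) on %d x %d\n",
              length(x$idx), prod(x$shape), observability(x), x$shape[1L], x$shape[2L]))
  invisible(x)
}

#' @export
length.observation_mask <- function(x) length(x$idx)

#' Entries of a mask as (row, column) pairs
#' @param mask an [observation_mask()].
#' @return integer matrix with columns `row`, `col`.
#' @export
mask_entries <- function(mask) {
  out <- arrayInd(mask$idx, mask$shape)
  colnames(out) <- c("row", "col")
  out
}

#' Sample a uniform random observation mask
#'
#' Draws exactly `round(observability * m * n)` distinct cells uniformly
#' without replacement, emulating random selection of checkpoint expression
#' values. The draw is fully determined by `seed`. No row/column coverage is
#' guaranteed unless `cover = TRUE`, which forces at least one observation in
#' every row and column (completion is ill-posed for entirely unobserved
#' rows or columns).
#'
#' @param m,n matrix dimensions.
#' @param observability target fraction of observed cells, in (0, 1].
#' @param seed integer seed.
#' @param cover logical; enforce >= 1 observation per row and per column.
#' @return an [observation_mask()].
#' @export
sample_mask <- function(m, n, observability, seed, cover = FALSE) {
  if (!is.numeric(observability) || length(observability) != 1L ||
      observability <= 0 || observability > 1)
    stop_("`observability` must lie in (0, 1]")
  m <- as.integer(m); n <- as.integer(n)
  total <- as.double(m) * n
  count <- round(observability * total)
  if (count < 1) stop_("observability %g selects no cells on %d x %d", observability, m, n)
  idx <- with_local_seed(seed, {
    if (!cover) {
      sample.int(total, count)
    } else {
      # guarantee one observation per row and per column, then fill uniformly
      base <- unique(c((sample.int(n, m, replace = TRUE) - 1L) * m + seq_len(m),
                       (seq_len(n) - 1L) * m + sample.int(m, n, replace = TRUE)))
      if (length(base) > count)
        stop_("observability %g too low to cover every row and column", observability)
      c(base, sample(setdiff(seq_len(total), base), count - length(base)))
    }
  })
  observation_mask(idx, m, n, seed = seed)
}

#' Fraction of observed cells
#'
#' The observability O of a mask is `|Omega| / (m * n)`: the fraction of
#' matrix entries known before prediction.
#'
#' @param mask an [observation_mask()].
#' @return a number in \[0, 1\].
#' @export
observability <- function(mask) {
  length(mask$idx) / prod(mask$shape)
}

#' Orthogonal projection onto the observed cells
#'
#' Returns a matrix equal to `x` on the mask and 0 elsewhere.
#'
#' @param mask an [observation_mask()].
#' @param x a numeric matrix (or [expression_matrix()]) of matching shape.
#' @return a numeric matrix.
#' @export
project <- function(mask, x) {
  v <- values_of(x)
  if (!all(dim(v) == mask$shape))
    stop_("matrix is %d x %d but mask is %d x %d",
          nrow(v), ncol(v), mask$shape[1L], mask$shape[2L])
  out <- array(0, dim = dim(v))
  out[mask$idx] <- v[mask$idx]
  dimnames(out) <- dimnames(v)
  out
}

#' Complement of a mask
#' @param mask an [observation_mask()].
#' @return an [observation_mask()] over the unobserved cells.
#' @export
mask_complement <- function(mask) {
  total <- prod(mask$shape)
  observation_mask(setdiff(seq_len(total), mask$idx), mask$shape[1L], mask$shape[2L])
}

#' Theoretical lower bound on the number of measurements
#'
#' For exact recovery of a rank-`r` matrix with `m` rows, nuclear-norm
#' minimisation requires on the order of `C * m^(6/5) * r * log(m)` uniformly
#' sampled entries, for a positive constant `C`. The caller compares the
#' returned value with the actual number of observed cells.
#'
#' @param m number of genes (rows), >= 2.
#' @param r assumed rank, >= 1.
#' @param C positive constant.
#' @return the bound (natural logarithm).
#' @export
sample_count_lower_bound <- function(m, r, C = 1) {
  if (m < 2) stop_("`m` must be >= 2")
  if (r < 1) stop_("`r` must be >= 1")
  if (C <= 0) stop_("`C` must be positive")
  C * m^(6 / 5) * r * log(m)
}
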