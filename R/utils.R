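#' @useDynLib annhypr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rbinom rpois runif sd mad median
#' @importFrom utils read.csv write.csv
NULL

# Seed-splitting scheme: every stochastic routine takes one user-visible seed;
# sub-streams are derived as split_seed(seed, stream), where `stream` is a
# small fixed integer documented at each call site.  Derived seeds stay inside
# the 32-bit integer range.
split_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((as.double(seed) * 1000003 + 7919 * stream) %% 2147483629) + 1L
}

# Replicate (edge-clamp) padding of a 3D array by `r` voxels on every side.
pad_replicate3 <- function(a, r) {
  d <- dim(a)
  ix <- pmin(pmax(seq_len(d[1] + 2 * r) - r, 1L), d[1])
  iy <- pmin(pmax(seq_len(d[2] + 2 * r) - r, 1L), d[2])
  iz <- pmin(pmax(seq_len(d[3] + 2 * r) - r, 1L), d[3])
  a[ix, iy, iz, drop = FALSE]
}

# Running mean along the first margin of a matrix whose rows were already
# replicate-padded by r: sums 2r+1 shifted row blocks (window small, so this
# beats per-column cumsum in R).
.window_mean_rows <- function(p, n, r) {
  acc <- p[seq_len(n), , drop = FALSE]
  if (r > 0) {
    for (o in seq_len(2 * r)) acc <- acc + p[o + seq_len(n), , drop = FALSE]
  }
  acc / (2 * r + 1)
}

# Apply a 1D sliding-window operation along one axis of a 3D array with
# replicate padding.  `fun(padded_matrix, n, r)` works on the first margin.
.along_axis3 <- function(a, axis, r, fun) {
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  b <- aperm(a, perm)
  d <- dim(b)
  n <- d[1]
  idx <- pmin(pmax(seq_len(n + 2 * r) - r, 1L), n)
  m <- matrix(b[idx, , ], nrow = n + 2 * r)
  out <- fun(m, n, r)
  dim(out) <- d
  aperm(out, order(perm))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_badarg <- function(...) stop(..., call. = FALSE)
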