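#' Frame weights for kinetic fitting
#'
#' Noise-equivalent-count style weighting: w_i proportional to
#' dt_i^2 / C_i, where C_i is the total image count of frame i — the
#' inverse-variance weight for count-normalized activity under Poisson
#' statistics.  Weights are normalized to sum to one.  A frame with zero
#' counts gets weight 0 with a warning.  Uniform weighting is available for
#' purely synthetic runs.
#'
#' @param counts_per_frame total image counts per frame.
#' @param schedule a \code{\link{frame_schedule}}.
#' @param method \code{"nec"} (default) or \code{"uniform"}.
#' @return An object of class \code{frame_weights} (numeric vector summing
#'   to 1).
#' @export
compute_frame_weights <- function(counts_per_frame, schedule,
                                  method = c("nec", "uniform")) {
  method <- match.arg(method)
  nf <- length(schedule)
  if (method == "uniform") {
    w <- rep(1 / nf, nf)
  } else {
    if (length(counts_per_frame) != nf)
      stop_badarg("counts_per_frame length must match the schedule")
    w <- numeric(nf)
    zero <- counts_per_frame <= 0
    if (any(zero))
      warning("frame(s) with zero counts get weight 0: ",
              paste(which(zero), collapse = ", "))
    dt <- durations(schedule)
    w[!zero] <- dt[!zero]^2 / counts_per_frame[!zero]
    w <- w / sum(w)
  }
  structure(w, class = "frame_weights")
}

#' Basis set for one-tissue-compartment fitting
#'
#' Precomputes, for a grid of washout rates k2, the frame-averaged
#' convolution Cp (x) exp(-k2 t) (unit K1), so that each candidate fit is
#' linear in K1.  The default grid is 100 log-spaced points over
#' [0.01, 1.0] min^-1.
#'
#' @param aif an \code{\link{input_function}} covering the schedule.
#' @param schedule a \code{\link{frame_schedule}}.
#' @param n_bases number of grid points (>= 2, default 100).
#' @param k2_range range of the washout grid in min^-1.
#' @param k2_grid optional explicit grid (overrides n_bases/k2_range).
#' @return An object of class \code{basis_set}: \code{k2_grid} and \code{B}
#'   (frames x bases matrix).
#' @export
build_basis <- function(aif, schedule, n_bases = 100,
                        k2_range = c(0.01, 1.0), k2_grid = NULL) {
  if (is.null(k2_grid)) {
    if (n_bases < 2) stop_badarg("n_bases must be at least 2")
    k2_grid <- exp(seq(log(k2_range[1]), log(k2_range[2]),
                       length.out = n_bases))
  }
  if (is.unsorted(k2_grid)) stop_badarg("k2_grid must be sorted ascending")
  B <- frame_average(convolve_exp(aif, k2_grid), aif, schedule)
  structure(list(k2_grid = k2_grid, B = as.matrix(B), schedule = schedule),
            class = "basis_set")
}

#' Fit one TAC with the basis function method
#'
#' For each grid value k2_j the amplitude is the weighted least-squares
#' solution through the origin, K1_j = sum(w B_j y) / sum(w B_j^2), clipped
#' at 0 (negative uptake is unphysical); the grid point minimizing the
#' weighted residual sum of squares is selected and VT = K1/k2 returned.
#' An all-zero TAC returns K1 = 0, k2 = the grid minimum, VT = 0 by
#' convention.
#'
#' @param tac per-frame activity vector.
#' @param basis a \code{\link{build_basis}} result.
#' @param weights a \code{\link{compute_frame_weights}} result (or any
#'   nonnegative per-frame weights).
#' @return List with \code{K1}, \code{k2}, \code{VT}, \code{wrss}.
#' @export
fit_tac_1t <- function(tac, basis, weights) {
  f <- fit_tac_matrix(matrix(tac, ncol = 1), basis, weights)
  list(K1 = f$K1[1], k2 = f$k2[1], VT = f$VT[1], wrss = f$wrss[1])
}

# Vectorized grid fit: Y is frames x V.
fit_tac_matrix <- function(Y, basis, weights) {
  w <- as.numeric(weights)
  B <- basis$B
  if (nrow(Y) != nrow(B))
    stop_badarg("TAC length does not match the basis frames")
  Bw <- B * w
  num <- crossprod(Bw, Y)                    # bases x V
  den <- colSums(B * Bw)                     # per-basis sum w B^2
  K1 <- pmax(num / den, 0)
  yss <- colSums(Y^2 * w)                    # V
  rss <- -2 * K1 * num + K1^2 * den
  rss <- sweep(rss, 2L, yss, `+`)
  jstar <- max.col(t(-rss), ties.method = "first")
  v <- seq_len(ncol(Y))
  pick <- cbind(jstar, v)
  K1s <- K1[pick]
  k2s <- basis$k2_grid[jstar]
  zero <- colSums(abs(Y)) == 0
  if (any(zero)) {
    K1s[zero] <- 0
    k2s[zero] <- basis$k2_grid[1]
  }
  list(K1 = K1s, k2 = k2s,
       VT = ifelse(K1s > 0, K1s / k2s, 0),
       wrss = rss[pick])
}

#' Voxel-wise parametric mapping
#'
#' Applies \code{\link{fit_tac_1t}} to every voxel inside the mask
#' (vectorized over the k2 grid); out-of-mask voxels are 0.
#'
#' @param dyn a \code{\link{dynamic_image}}.
#' @param basis a \code{\link{build_basis}} result.
#' @param weights per-frame weights.
#' @param mask 3D logical array matching the volume.
#' @return An object of class \code{parametric_maps} with 3D volumes
#'   \code{K1} (mL cm^-3 min^-1), \code{k2} (min^-1), \code{VT} (mL cm^-3)
#'   and \code{wrss}.
#' @export
fit_parametric <- function(dyn, basis, weights, mask = NULL) {
  d <- dim(dyn)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  if (!identical(dim(mask), d[1:3]))
    stop_badarg("mask shape does not match the image volume")
  idx <- which(mask)
  if (length(idx) == 0L) stop_badarg("empty mask")
  nf <- d[4]
  Y <- matrix(0, nf, length(idx))
  for (i in seq_len(nf)) Y[i, ] <- get_frame(dyn, i)[idx]
  f <- fit_tac_matrix(Y, basis, weights)
  mk <- function(v) { a <- array(0, d[1:3]); a[idx] <- v; a }
  structure(list(K1 = mk(f$K1), k2 = mk(f$k2), VT = mk(f$VT),
                 wrss = mk(f$wrss), mask = mask),
            class = "parametric_maps")
}

#' @export
print.parametric_maps <- function(x, ...) {
  m <- x$mask
  cat(sprintf("Parametric maps over %d voxels\n", sum(m)))
  cat(sprintf("  K1: %.4g-%.4g mL/cm^3/min,  VT: %.4g-%.4g mL/cm^3\n",
              min(x$K1[m]), max(x$K1[m]), min(x$VT[m]), max(x$VT[m])))
  invisible(x)
}

#' @export
summary.parametric_maps <- function(object, ...) {
  m <- object$mask
  out <- rbind(K1 = summary(object$K1[m]),
               k2 = summary(object$k2[m]),
               VT = summary(object$VT[m]))
  out
}
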