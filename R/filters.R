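#' Cubic box (uniform mean) filter
#'
#' Separable uniform mean over a size^3 neighborhood with replicate padding
#' at the borders.  \code{size} must be odd; size 1 is the identity.
#'
#' @param vol 3D numeric array.
#' @param size odd integer edge length of the cubic window (voxels).
#' @return Filtered 3D array of the same shape.
#' @export
box_filter <- function(vol, size) {
  if (length(size) != 1L || size < 1 || size %% 2 == 0)
    stop_badarg("box filter size must be a positive odd integer")
  if (size == 1) return(vol)
  r <- (size - 1L) / 2L
  for (ax in 1:3) vol <- .along_axis3(vol, ax, r, .window_mean_rows)
  vol
}

#' 3D Gaussian filter parameterized by FWHM in mm
#'
#' Isotropic Gaussian convolution with sigma = FWHM / (2 sqrt(2 ln 2)) per
#' axis, converted to voxel units via \code{voxel_size}; replicate padding at
#' the borders.  The discrete kernel is the sampled Gaussian truncated at
#' 4 sigma and normalized to unit sum.
#'
#' @param vol 3D numeric array.
#' @param fwhm full width at half maximum in mm (>= 0; 0 is the identity).
#' @param voxel_size voxel edge lengths in mm (length 1 or 3).
#' @return Filtered 3D array of the same shape.
#' @export
gaussian_filter_fwhm <- function(vol, fwhm, voxel_size = 2) {
  if (fwhm < 0) stop_badarg("fwhm must be nonnegative")
  if (fwhm == 0) return(vol)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3)
  sig <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size
  for (ax in 1:3) {
    s <- sig[ax]
    r <- max(1L, ceiling(4 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    vol <- .along_axis3(vol, ax, r, function(p, n, rr) {
      acc <- k[1] * p[seq_len(n), , drop = FALSE]
      for (o in seq_len(2 * rr))
        acc <- acc + k[o + 1] * p[o + seq_len(n), , drop = FALSE]
      acc
    })
  }
  vol
}

#' Apply the Gaussian filter to every frame of a dynamic series
#'
#' @param dyn a \code{\link{dynamic_image}}.
#' @param fwhm FWHM in mm.
#' @return A \code{\link{dynamic_image}}.
#' @export
gaussian_series <- function(dyn, fwhm) {
  map_frames(dyn, function(fr, i)
    gaussian_filter_fwhm(fr, fwhm, dyn$voxel_size))
}
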