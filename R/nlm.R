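#' Configuration for spatiotemporal non-local means
#'
#' @param search_spatial odd search-window extent per spatial axis
#'   (default 11).
#' @param search_temporal odd search extent in frames (default 7).
#' @param nb_spatial odd neighborhood extent per spatial axis (default 7);
#'   must not exceed the spatial search extent.
#' @param nb_temporal odd neighborhood extent in frames (default 7).
#' @param smoothing_constant unitless multiplier of the estimated noise
#'   level forming the bandwidth h (typical sweep: 0.5, 1.0, 1.5).
#' @param temporal_window \code{"centered"} slides a clamped
#'   \code{search_temporal}-frame window over the series;
#'   \code{"fixed-range"} uses one fixed frame block (\code{fixed_frames},
#'   1-based, default 9:15) for every target frame.
#' @param fixed_frames 1-based frame range for \code{"fixed-range"}.
#' @return An object of class \code{nlm_config}.
#' @export
nlm_config <- function(search_spatial = 11, search_temporal = 7,
                       nb_spatial = 7, nb_temporal = 7,
                       smoothing_constant = 1.0,
                       temporal_window = c("centered", "fixed-range"),
                       fixed_frames = 9:15) {
  temporal_window <- match.arg(temporal_window)
  ext <- c(search_spatial, search_temporal, nb_spatial, nb_temporal)
  if (any(ext < 1) || any(ext %% 2 == 0))
    stop_badarg("all window extents must be odd positive integers")
  if (nb_spatial > search_spatial)
    stop_badarg("neighborhood must not exceed the search window spatially")
  structure(list(search_spatial = as.integer(search_spatial),
                 search_temporal = as.integer(search_temporal),
                 nb_spatial = as.integer(nb_spatial),
                 nb_temporal = as.integer(nb_temporal),
                 smoothing_constant = smoothing_constant,
                 temporal_window = temporal_window,
                 fixed_frames = as.integer(fixed_frames)),
            class = "nlm_config")
}

# Robust per-frame noise-level estimate: MAD of the first-difference field
# along x divided by sqrt(2) (first differences of iid noise have twice the
# variance of the noise itself).  Differences where both voxels are zero
# (empty background, common in simulated or masked data) carry no noise
# information and would drag the median to zero, so they are excluded.
.frame_sigma <- function(dyn) {
  nf <- dim(dyn)[4]
  vapply(seq_len(nf), function(i) {
    fr <- get_frame(dyn, i)
    n1 <- dim(fr)[1]
    a <- fr[-1, , ]; b <- fr[-n1, , ]
    d <- (a - b)[a != 0 | b != 0]
    if (length(d) < 2L) return(0)
    mad(d, center = 0) / sqrt(2)
  }, numeric(1))
}

#' Spatiotemporal non-local means denoising
#'
#' Each output voxel is the similarity-weighted average of the voxels in its
#' 4D search window; the weight of a candidate is
#' w = exp(-d^2 / h^2), where d^2 is the mean squared difference between the
#' two 4D neighborhood windows (replicate-clamped at the borders) and
#' h = \code{smoothing_constant} x sigma-hat.  Sigma-hat is a robust
#' per-frame noise estimate (MAD of the first-difference field / sqrt(2))
#' averaged over the temporal window of the target frame.  The center voxel
#' participates with a weight computed like any other; weights are
#' normalized to sum to one, so every output value is a convex combination
#' of its search window.
#'
#' @param dyn a \code{\link{dynamic_image}}.
#' @param cfg an \code{\link{nlm_config}}.
#' @return A \code{\link{dynamic_image}}.
#' @export
nlm_st <- function(dyn, cfg = nlm_config()) {
  d <- dim(dyn)
  sig <- .frame_sigma(dyn)
  nt <- d[4]
  if (cfg$temporal_window == "fixed-range") {
    fr <- cfg$fixed_frames
    if (min(fr) < 1 || max(fr) > nt)
      stop_badarg("fixed_frames outside the series (1..", nt, ")")
    t_lo <- min(fr) - 1L; t_hi <- max(fr) - 1L
    h <- cfg$smoothing_constant * rep(mean(sig[fr]), nt)
  } else {
    t_lo <- -1L; t_hi <- -1L
    rt <- (cfg$search_temporal - 1L) / 2L
    h <- cfg$smoothing_constant * vapply(seq_len(nt), function(t) {
      win <- max(1L, t - rt):min(nt, t + rt)
      mean(sig[win])
    }, numeric(1))
  }
  out <- nlm_st_cpp(dyn$frames, as.integer(d),
                    cfg$search_spatial, cfg$search_temporal,
                    cfg$nb_spatial, cfg$nb_temporal,
                    h, t_lo, t_hi)
  dynamic_image(array(out, d), dyn$schedule, dyn$voxel_size)
}
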