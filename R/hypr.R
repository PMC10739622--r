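#' Duration-weighted composite image
#'
#' The HYPR composite: the duration-weighted mean of all frames,
#' C = sum_i dt_i I_i / sum_i dt_i.  Using the full series gives the
#' composite its high signal-to-noise ratio.
#'
#' @param dyn a \code{\link{dynamic_image}} with at least one frame.
#' @return 3D numeric array.
#' @export
composite_image <- function(dyn) {
  nf <- dim(dyn)[4]
  if (nf < 1L) stop_badarg("empty dynamic series")
  dt <- durations(dyn$schedule)
  acc <- get_frame(dyn, 1) * dt[1]
  if (nf > 1) for (i in 2:nf) acc <- acc + get_frame(dyn, i) * dt[i]
  acc / sum(dt)
}

#' HYPR composite-ratio processing of a dynamic series
#'
#' For each frame i the weighting image is the ratio of the box-filtered
#' frame to the box-filtered composite, W_i = F(I_i) / F(C), and the output
#' frame is H_i = C x W_i.  Where |F(C)| falls below
#' \code{eps_frac x max(C)} the weight is set to 1 so the output falls back
#' to the composite (this guards empty background against noise
#' amplification).
#'
#' @param dyn a \code{\link{dynamic_image}}.
#' @param box_size odd box-filter edge length in voxels (default 7).
#' @param eps_frac relative threshold of the division guard.
#' @return A \code{\link{dynamic_image}} with the schedule preserved.
#' @export
hypr_process <- function(dyn, box_size = 7, eps_frac = 1e-9) {
  comp <- composite_image(dyn)
  fc <- box_filter(comp, box_size)
  eps <- eps_frac * max(abs(comp))
  good <- abs(fc) >= eps
  map_frames(dyn, function(fr, i) {
    w <- array(1, dim(fr))
    w[good] <- box_filter(fr, box_size)[good] / fc[good]
    comp * w
  })
}

#' Combined ANN + HYPR spatiotemporal denoising
#'
#' Applies the trained patch ANN in cascade to every frame, then HYPR
#' composite-ratio filtering to the ANN-processed series.
#'
#' @param model a trained \code{\link{ann_model}}.
#' @param dyn a \code{\link{dynamic_image}}.
#' @param passes number of cascade ANN applications (default 3).
#' @param box_size HYPR box-filter size (default 7).
#' @return A \code{\link{dynamic_image}}.
#' @export
ann_hypr <- function(model, dyn, passes = 3, box_size = 7) {
  hypr_process(denoise_series(model, dyn, passes), box_size)
}
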