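#' Ensemble normalized standard deviation (EnNSD)
#'
#' Voxel-level noise across noise realizations: for each ROI voxel the
#' sample standard deviation across the J realizations (divisor J - 1)
#' divided by the across-realization mean, averaged over the ROI's voxels,
#' reported in percent.  Voxels whose across-realization mean magnitude
#' falls below \code{eps_frac} times the maximum of the mean image are
#' excluded; the excluded count is attached as attribute
#' \code{"n_excluded"}.
#'
#' @param realizations list of >= 2 co-registered numeric arrays (any shape).
#' @param roi integer/logical index of the ROI voxels.
#' @param eps_frac relative mean-magnitude guard (default 1e-6).
#' @return EnNSD in percent.
#' @export
ennsd <- function(realizations, roi, eps_frac = 1e-6) {
  J <- length(realizations)
  if (J < 2L) stop_badarg("need at least 2 realizations")
  vals <- vapply(realizations, function(a) as.numeric(a[roi]),
                 numeric(length(which_roi(realizations[[1]], roi))))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  mu <- rowMeans(vals)
  s <- sqrt(rowSums((vals - mu)^2) / (J - 1))
  # the guard threshold references the whole image, not just the ROI
  gmax <- max(abs(Reduce(`+`, realizations))) / J
  eps <- eps_frac * gmax
  keep <- abs(mu) >= eps
  if (!any(keep))
    stop_badarg("all ROI voxels excluded by the near-zero-mean guard")
  out <- mean(s[keep] / mu[keep]) * 100
  attr(out, "n_excluded") <- sum(!keep)
  out
}

which_roi <- function(a, roi) {
  if (is.logical(roi)) which(roi) else roi
}

#' Relative error of the regional mean (RE)
#'
#' For each realization the ROI mean is compared with the full-count
#' reference ROI mean, (mean_j - mean_full) / mean_full; the result is the
#' average over realizations, in percent.
#'
#' @param realizations list of numeric arrays.
#' @param reference the full-count counterpart array.
#' @param roi ROI voxel index.
#' @return RE in percent.
#' @export
regional_re <- function(realizations, reference, roi) {
  ref <- mean(reference[roi])
  if (ref == 0) stop_badarg("reference ROI mean is zero")
  mean(vapply(realizations, function(a) (mean(a[roi]) - ref) / ref,
              numeric(1))) * 100
}

#' Noise reduction (NR)
#'
#' Percent reduction of EnNSD achieved by a denoiser relative to the raw
#' reduced-count data: (EnNSD_raw - EnNSD_processed) / EnNSD_raw x 100.
#'
#' @param ennsd_raw EnNSD of the unprocessed reduced-count data (percent,
#'   > 0).
#' @param ennsd_processed EnNSD after processing (percent).
#' @return NR in percent.
#' @export
noise_reduction <- function(ennsd_raw, ennsd_processed) {
  if (any(ennsd_raw <= 0)) stop_badarg("ennsd_raw must be positive")
  (ennsd_raw - ennsd_processed) / ennsd_raw * 100
}

#' Poisson dose-equivalence of a noise reduction
#'
#' Under Poisson counting statistics the noise standard deviation scales as
#' 1/sqrt(dose), so a fractional noise reduction NR is statistically
#' equivalent to a dose increase of 1 / (1 - NR)^2.
#'
#' @param nr_fraction fractional noise reduction in [0, 1).
#' @return Equivalent dose fold-increase.
#' @examples
#' dose_equivalence_factor(0.75)  # 16
#' @export
dose_equivalence_factor <- function(nr_fraction) {
  if (any(nr_fraction < 0) || any(nr_fraction >= 1))
    stop_badarg("nr_fraction must lie in [0, 1)")
  1 / (1 - nr_fraction)^2
}

#' Noise-versus-bias sweep over denoising methods
#'
#' Applies each method to every reduced-count realization, computes EnNSD
#' and RE per ROI for the requested frames and (optionally) for K1/VT
#' parametric maps fitted from the processed series, and tabulates NR
#' against the raw rows.
#'
#' @param realizations list of reduced-count \code{\link{dynamic_image}}s.
#' @param reference the full-count \code{\link{dynamic_image}} (unprocessed;
#'   the bias reference).
#' @param regions a \code{\link{region_map}}.
#' @param methods named list; each element is
#'   \code{list(fun = function(dyn) ..., parameter = "label")}.  An entry
#'   named \code{"raw"} with \code{fun = identity} is added if absent.
#' @param frames 1-based frame indices to report (default the
#'   highest-count and last frames, 12 and 21, for the standard protocol).
#' @param fit optional list \code{list(basis =, weights =)} enabling
#'   parametric-map evaluation (targets \code{"K1"} and \code{"VT"}).
#' @return \code{data.frame} with columns \code{method}, \code{parameter},
#'   \code{roi}, \code{target}, \code{ennsd_pct}, \code{re_pct},
#'   \code{nr_pct}.
#' @export
noise_bias_sweep <- function(realizations, reference, regions,
                             methods, frames = c(12, 21), fit = NULL) {
  shapes <- vapply(realizations, function(d) paste(dim(d), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1L ||
      shapes[1] != paste(dim(reference), collapse = "x"))
    stop_badarg("all realizations and the reference must share one shape")
  if (!"raw" %in% names(methods))
    methods <- c(list(raw = list(fun = identity, parameter = "")), methods)
  labs <- sort(unique(as.vector(regions$labels[regions$labels > 0])))
  rois <- lapply(labs, function(l) which(regions$labels == l))
  names(rois) <- vapply(as.character(labs), function(l)
    regions$region_names[[l]], character(1))
  mask <- regions$labels > 0

  rows <- list()
  for (mn in names(methods)) {
    m <- methods[[mn]]
    proc <- lapply(realizations, m$fun)
    targets <- list()
    for (f in frames)
      targets[[paste0("frame", f)]] <-
        list(stack = lapply(proc, get_frame, i = f),
             ref = get_frame(reference, f))
    if (!is.null(fit)) {
      maps <- lapply(proc, fit_parametric, basis = fit$basis,
                     weights = fit$weights, mask = mask)
      ref_maps <- fit_parametric(reference, fit$basis, fit$weights, mask)
      targets[["K1"]] <- list(stack = lapply(maps, `[[`, "K1"),
                              ref = ref_maps$K1)
      targets[["VT"]] <- list(stack = lapply(maps, `[[`, "VT"),
                              ref = ref_maps$VT)
    }
    for (tn in names(targets)) {
      tg <- targets[[tn]]
      for (rn in names(rois)) {
        rows[[length(rows) + 1L]] <- data.frame(
          method = mn, parameter = m$parameter %||% "", roi = rn,
          target = tn,
          ennsd_pct = as.numeric(ennsd(tg$stack, rois[[rn]])),
          re_pct = regional_re(tg$stack, tg$ref, rois[[rn]]))
      }
    }
  }
  out <- do.call(rbind, rows)
  raw <- out[out$method == "raw", c("roi", "target", "ennsd_pct")]
  names(raw)[3] <- "ennsd_raw"
  out <- merge(out, raw, by = c("roi", "target"), sort = FALSE)
  out$nr_pct <- noise_reduction(out$ennsd_raw, out$ennsd_pct)
  out$ennsd_raw <- NULL
  out[order(match(out$method, names(methods)), out$target, out$roi), ]
}

#' Find the Gaussian FWHM matching a target noise level
#'
#' Bisects on the FWHM so that the EnNSD of the filtered frame (over the
#' given ROI voxels, across realizations) matches \code{target_ennsd} — the
#' matched-noise protocol used to compare Gaussian smoothing against the
#' ANN cascade.
#'
#' @param realizations list of reduced-count \code{\link{dynamic_image}}s.
#' @param frame 1-based frame index used for matching.
#' @param roi ROI voxel index over which EnNSD is evaluated.
#' @param target_ennsd target EnNSD in percent.
#' @param interval FWHM search interval in mm.
#' @param tol EnNSD tolerance in percentage points.
#' @return Matched FWHM in mm.
#' @export
match_gaussian_fwhm <- function(realizations, frame, roi, target_ennsd,
                                interval = c(0.1, 12), tol = 0.05) {
  vx <- realizations[[1]]$voxel_size
  frames <- lapply(realizations, get_frame, i = frame)
  f_ennsd <- function(fwhm)
    ennsd(lapply(frames, gaussian_filter_fwhm, fwhm = fwhm,
                 voxel_size = vx), roi)
  lo <- interval[1]; hi <- interval[2]
  if (f_ennsd(hi) > target_ennsd) return(hi)
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    e <- f_ennsd(mid)
    if (abs(e - target_ennsd) < tol) return(mid)
    if (e > target_ennsd) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
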