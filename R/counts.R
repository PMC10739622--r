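#' Count model for Poisson noise simulation
#'
#' Maps activity (Bq/mL) to expected detected counts per voxel and frame:
#' lambda = activity x sensitivity x frame duration.  Radioactive decay is
#' ignored (reconstructed images are decay-corrected), so a single scalar
#' sensitivity suffices.
#'
#' @param sensitivity expected counts per (Bq/mL) x min per voxel at full
#'   dose.
#' @param dose_fraction fraction of the full dose per reduced realization,
#'   in (0, 1]; the standard protocol uses 1/10.
#' @param n_realizations number of reduced-count realizations (default 10).
#' @param seed integer seed for the Poisson draws.
#' @param mode \code{"partition"} splits one full-count draw into disjoint
#'   subsets by multinomial thinning (emulating list-mode event
#'   redistribution); \code{"independent"} draws each realization
#'   independently.
#' @return An object of class \code{count_model}.
#' @export
count_model <- function(sensitivity, dose_fraction = 1 / 10,
                        n_realizations = 10, seed = 1,
                        mode = c("partition", "independent")) {
  mode <- match.arg(mode)
  if (sensitivity <= 0) stop_badarg("sensitivity must be positive")
  if (dose_fraction <= 0 || dose_fraction > 1)
    stop_badarg("dose_fraction must be in (0, 1]")
  structure(list(sensitivity = sensitivity, dose_fraction = dose_fraction,
                 n_realizations = as.integer(n_realizations),
                 seed = as.integer(seed), mode = mode),
            class = "count_model")
}

#' Calibrate the scanner sensitivity to a target count level
#'
#' Chooses the sensitivity so that, at full dose, the longest-duration frames
#' of the noise-free image average \code{target_counts} expected counts per
#' in-object voxel.  This sets the noise regime of the reduced-count
#' realizations.
#'
#' @param img noise-free \code{\link{dynamic_image}}.
#' @param target_counts mean expected counts per voxel in the
#'   longest-duration full-count frames (default 50).
#' @return Scalar sensitivity (counts per (Bq/mL) x min).
#' @export
calibrate_sensitivity <- function(img, target_counts = 50) {
  dur <- durations(img$schedule)
  long <- which(dur == max(dur))
  mask <- get_frame(img, long[1]) > 0
  lam <- 0
  for (i in long) lam <- lam + mean(get_frame(img, i)[mask]) * dur[i]
  target_counts * length(long) / lam
}

#' Full-count and reduced-count Poisson realizations
#'
#' Per voxel and frame the expected count is
#' lambda = activity x sensitivity x duration; one Poisson draw at lambda
#' gives the full-count sample.  In \code{"partition"} mode the draw is split
#' into \code{n_realizations} disjoint subsets by multinomial thinning with
#' equal probabilities, mirroring sequential event redistribution in
#' list-mode data (the subsets sum exactly to the full-count draw and are
#' marginally Poisson with mean lambda x dose_fraction).  Counts are
#' converted back to activity by dividing by
#' sensitivity x duration x dose_fraction.
#'
#' @param img nonnegative noise-free \code{\link{dynamic_image}}.
#' @param counts a \code{\link{count_model}}.
#' @param keep_counts if TRUE, attach the integer count arrays as attribute
#'   \code{"counts"} (a list with \code{full} and \code{reduced}).
#' @return A list of class \code{realization_set}: \code{full} (a
#'   \code{dynamic_image}), \code{reduced} (list of \code{dynamic_image}),
#'   and \code{counts_model}.
#' @export
poisson_realizations <- function(img, counts, keep_counts = FALSE) {
  if (min(img$frames) < 0) stop_badarg("activity image must be nonnegative")
  n <- counts$n_realizations
  if (counts$mode == "partition" &&
      abs(counts$dose_fraction * n - 1) > 1e-9)
    stop_badarg("partition mode requires dose_fraction x n_realizations = 1")
  dur <- durations(img$schedule)
  d <- dim(img$frames)
  lam <- img$frames * counts$sensitivity *
    array(rep(dur, each = prod(d[1:3])), d)
  set.seed(split_seed(counts$seed, 1L))  # stream 1: count draws
  if (counts$mode == "partition") {
    full_n <- array(rpois(length(lam), lam), d)
    remaining <- full_n
    reduced_n <- vector("list", n)
    for (j in seq_len(n - 1)) {
      # successive binomial thinning = equal-probability multinomial split
      reduced_n[[j]] <- array(rbinom(length(remaining), remaining,
                                     1 / (n - j + 1)), d)
      remaining <- remaining - reduced_n[[j]]
    }
    reduced_n[[n]] <- remaining
  } else {
    full_n <- array(rpois(length(lam), lam), d)
    reduced_n <- lapply(seq_len(n), function(j)
      array(rpois(length(lam), lam * counts$dose_fraction), d))
  }
  denom <- counts$sensitivity * array(rep(dur, each = prod(d[1:3])), d)
  to_img <- function(cnt, frac)
    dynamic_image(cnt / (denom * frac), img$schedule, img$voxel_size)
  out <- structure(
    list(full = to_img(full_n, 1),
         reduced = lapply(reduced_n, to_img, frac = counts$dose_fraction),
         count_model = counts),
    class = "realization_set")
  if (keep_counts)
    attr(out, "counts") <- list(full = full_n, reduced = reduced_n)
  out
}

#' @export
print.realization_set <- function(x, ...) {
  cat(sprintf(
    "Realization set: 1 full-count + %d x %.3g-count series (%s mode)\n",
    length(x$reduced), x$count_model$dose_fraction, x$count_model$mode))
  invisible(x)
}
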