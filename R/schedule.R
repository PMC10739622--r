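#' Frame schedule of a dynamic PET acquisition
#'
#' A frame schedule records the start and end time (in minutes) of every
#' reconstructed frame.  Frames must be contiguous, non-overlapping, start at
#' zero and have positive duration.
#'
#' @param frame_start numeric vector of frame start times in minutes.
#' @param frame_end numeric vector of frame end times in minutes.
#' @return An object of class \code{frame_schedule} with elements
#'   \code{frame_start}, \code{frame_end} and \code{duration} (minutes).
#' @examples
#' sch <- frame_schedule(c(0, 0.5), c(0.5, 1))
#' durations(sch)
#' @export
frame_schedule <- function(frame_start, frame_end) {
  if (length(frame_start) != length(frame_end) || length(frame_start) < 1L)
    stop_badarg("frame_start and frame_end must be nonempty and equal length")
  if (frame_start[1] != 0)
    stop_badarg("first frame must start at 0 min")
  dur <- frame_end - frame_start
  if (any(dur <= 0))
    stop_badarg("all frame durations must be positive")
  if (length(frame_start) > 1L &&
      any(abs(frame_start[-1] - frame_end[-length(frame_end)]) > 1e-9))
    stop_badarg("frames must be contiguous and non-overlapping")
  structure(
    list(frame_start = as.double(frame_start),
         frame_end = as.double(frame_end),
         duration = as.double(dur)),
    class = "frame_schedule")
}

#' Default 60-min, 21-frame acquisition protocol
#'
#' The standard dynamic protocol used throughout the package: frame durations
#' 6 x 30 s, 3 x 1 min, 2 x 2 min and 10 x 5 min, totalling 60 minutes over
#' 21 frames.
#'
#' @return A \code{\link{frame_schedule}} with 21 frames.
#' @export
default_schedule <- function() {
  dur <- c(rep(0.5, 6), rep(1, 3), rep(2, 2), rep(5, 10))
  ends <- cumsum(dur)
  frame_schedule(c(0, ends[-length(ends)]), ends)
}

#' @export
length.frame_schedule <- function(x) length(x$frame_start)

#' Frame durations in minutes
#' @param schedule a \code{\link{frame_schedule}}.
#' @return Numeric vector of per-frame durations (min).
#' @export
durations <- function(schedule) schedule$duration

#' Frame mid-times in minutes
#' @param schedule a \code{\link{frame_schedule}}.
#' @return Numeric vector of frame midpoints (min).
#' @export
midtimes <- function(schedule) (schedule$frame_start + schedule$frame_end) / 2

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("Frame schedule: %d frames, %.1f min total\n",
              length(x), x$frame_end[length(x)]))
  cat("  durations (min):", paste(format(x$duration), collapse = " "), "\n")
  invisible(x)
}
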