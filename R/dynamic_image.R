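#' Dynamic PET image series
#'
#' A 4D activity array (Bq/mL) bound to a \code{\link{frame_schedule}} and a
#' voxel geometry.  The frame axis is last (x, y, z, frame).
#'
#' @param frames 4D numeric array, frame axis last.
#' @param schedule a \code{\link{frame_schedule}}; its length must equal the
#'   4th dimension of \code{frames}.
#' @param voxel_size voxel edge lengths in mm (length 1 or 3).
#' @return An object of class \code{dynamic_image}.
#' @export
dynamic_image <- function(frames, schedule, voxel_size = 2) {
  d <- dim(frames)
  if (length(d) != 4L)
    stop_badarg("frames must be a 4D array (x, y, z, frame)")
  if (d[4] != length(schedule))
    stop_badarg("frame count (", d[4], ") does not match schedule length (",
                length(schedule), ")")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3)
  structure(list(frames = frames, schedule = schedule,
                 voxel_size = as.double(voxel_size)),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "Dynamic image: %d x %d x %d voxels (%s mm), %d frames, %.1f min\n",
    d[1], d[2], d[3], paste(format(x$voxel_size), collapse = " x "),
    d[4], x$schedule$frame_end[length(x$schedule)]))
  cat(sprintf("  activity range: %.4g to %.4g Bq/mL\n",
              min(x$frames), max(x$frames)))
  invisible(x)
}

#' @export
dim.dynamic_image <- function(x) dim(x$frames)

#' Extract one frame as a 3D array
#' @param dyn a \code{\link{dynamic_image}}.
#' @param i frame index (1-based).
#' @return 3D numeric array.
#' @export
get_frame <- function(dyn, i) {
  fr <- dyn$frames[, , , i, drop = FALSE]
  dim(fr) <- dim(fr)[1:3]   # drop only the frame axis
  fr
}

# Replace every frame of a dynamic image via a function of the 3D frame.
map_frames <- function(dyn, fun) {
  out <- dyn$frames
  for (i in seq_len(dim(out)[4])) out[, , , i] <- fun(get_frame(dyn, i), i)
  dynamic_image(out, dyn$schedule, dyn$voxel_size)
}

#' Regional mean time-activity curves
#'
#' @param dyn a \code{\link{dynamic_image}}.
#' @param regions a \code{\link{region_map}} (or integer label volume).
#' @return Matrix of regional mean activity, frames x regions, with region
#'   labels as column names.
#' @export
regional_tac <- function(dyn, regions) {
  labels <- if (inherits(regions, "region_map")) regions$labels else regions
  labs <- sort(unique(labels[labels > 0]))
  nf <- dim(dyn)[4]
  out <- matrix(0, nf, length(labs),
                dimnames = list(NULL, as.character(labs)))
  for (j in seq_along(labs)) {
    idx <- which(labels == labs[j])
    for (i in seq_len(nf)) out[i, j] <- mean(get_frame(dyn, i)[idx])
  }
  out
}
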