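#' Read / write a dynamic series as 4D NIfTI plus a JSON sidecar
#'
#' The NIfTI-1 file carries the 4D activity array (Bq/mL) and the voxel
#' geometry; the sidecar \code{<path>.json} holds
#' \code{frame_start_min} / \code{frame_end_min}.  The round-trip is
#' lossless for data, schedule and voxel size.
#'
#' @param dyn a \code{\link{dynamic_image}}.
#' @param path path of the NIfTI file (\code{.nii} or \code{.nii.gz}); the
#'   sidecar is written next to it.
#' @return \code{read_dynamic} returns a \code{dynamic_image};
#'   \code{write_dynamic} returns \code{path} invisibly.
#' @export
write_dynamic <- function(dyn, path) {
  img <- RNifti::asNifti(dyn$frames)
  RNifti::pixdim(img) <- c(dyn$voxel_size, 1)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(frame_start_min = dyn$schedule$frame_start,
         frame_end_min = dyn$schedule$frame_end),
    sidecar_path(path), digits = NA)
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' @rdname write_dynamic
#' @export
read_dynamic <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop_badarg("missing frame-schedule sidecar: ", sp)
  sc <- jsonlite::read_json(sp, simplifyVector = TRUE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  nf <- dim(arr)[4]
  if (length(sc$frame_start_min) != nf)
    stop_badarg("sidecar ", sp, " lists ", length(sc$frame_start_min),
                " frames but ", path, " holds ", nf)
  if (!all(is.finite(arr)))
    stop_badarg("non-finite voxel values in ", path)
  vx <- attr(img, "pixdim")[1:3]
  dynamic_image(array(as.numeric(arr), dim(arr)),
                frame_schedule(sc$frame_start_min, sc$frame_end_min), vx)
}

#' Read / write a region map as integer NIfTI plus a JSON label table
#'
#' @param regions a \code{\link{region_map}}.
#' @param path NIfTI path; the label table goes to \code{<path>.json}.
#' @return \code{read_region_map} returns a \code{region_map}.
#' @export
write_region_map <- function(regions, path) {
  img <- RNifti::asNifti(regions$labels + 0L)
  RNifti::pixdim(img) <- regions$voxel_size
  RNifti::writeNifti(img, path, datatype = "int16")
  jsonlite::write_json(as.list(regions$region_names), sidecar_path(path),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_region_map
#' @export
read_region_map <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop_badarg("missing label table: ", sp)
  nm <- unlist(jsonlite::read_json(sp, simplifyVector = TRUE))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  region_map(array(as.integer(round(arr)), dim(arr)),
             attr(img, "pixdim")[1:3], nm)
}

#' Write parametric maps as one NIfTI volume per parameter
#'
#' @param maps a \code{\link{fit_parametric}} result.
#' @param dir output directory (created if needed).
#' @param voxel_size mm per axis.
#' @return The directory, invisibly.
#' @export
write_parametric_maps <- function(maps, dir, voxel_size = 2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3)
  for (nm in c("K1", "k2", "VT", "wrss")) {
    img <- RNifti::asNifti(maps[[nm]])
    RNifti::pixdim(img) <- voxel_size
    RNifti::writeNifti(img, file.path(dir, paste0(nm, ".nii.gz")))
  }
  invisible(dir)
}
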