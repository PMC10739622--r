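#' Region label map
#'
#' Integer label volume with voxel geometry and a label -> name table.
#' Label 0 is background.
#'
#' @param labels 3D integer array; 0 = background.
#' @param voxel_size mm per axis (length 1 or 3).
#' @param region_names named character vector mapping label (as name) to
#'   region name.
#' @return An object of class \code{region_map}.
#' @export
region_map <- function(labels, voxel_size = 2, region_names = NULL) {
  if (length(dim(labels)) != 3L) stop_badarg("labels must be a 3D array")
  labs <- sort(unique(as.vector(labels[labels > 0])))
  if (is.null(region_names))
    region_names <- stats::setNames(paste0("region_", labs),
                                    as.character(labs))
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3)
  structure(list(labels = labels, voxel_size = as.double(voxel_size),
                 region_names = region_names),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  d <- dim(x$labels)
  labs <- sort(unique(as.vector(x$labels[x$labels > 0])))
  cat(sprintf("Region map: %d x %d x %d voxels, %d regions\n",
              d[1], d[2], d[3], length(labs)))
  for (l in labs)
    cat(sprintf("  %2d %-14s %6d voxels\n", l,
                x$region_names[[as.character(l)]], sum(x$labels == l)))
  invisible(x)
}

#' Per-region one-tissue-compartment ground truth
#'
#' @param K1 named numeric vector of uptake rates (mL cm^-3 min^-1), names are
#'   region labels.
#' @param k2 named numeric vector of washout rates (min^-1), same names.
#' @return An object of class \code{kinetic_truth} with a derived VT = K1/k2.
#' @export
kinetic_truth <- function(K1, k2) {
  if (!identical(names(K1), names(k2)) || is.null(names(K1)))
    stop_badarg("K1 and k2 must be named by region label, identically")
  if (any(K1 < 0)) stop_badarg("K1 must be nonnegative")
  if (any(k2 < 0.01 - 1e-12) || any(k2 > 1 + 1e-12))
    stop_badarg("k2 must lie within the fitting range [0.01, 1.0] min^-1")
  structure(list(K1 = K1, k2 = k2, VT = K1 / k2), class = "kinetic_truth")
}

#' Default brain-like region geometry
#'
#' Builds a six-region brain-like label volume (cortex shell, white matter,
#' thalamus, caudate, putamen, cerebellum) from nested ellipsoids, scaled to
#' any grid size.  Geometry is defined in normalized coordinates so the same
#' anatomy renders at any resolution.
#'
#' @param dim grid size (x, y, z), default 64 x 64 x 48.
#' @param voxel_size mm per axis.
#' @return A \code{\link{region_map}}.
#' @export
brain_region_map <- function(dim = c(64, 64, 48), voxel_size = 2) {
  nx <- dim[1]; ny <- dim[2]; nz <- dim[3]
  u <- function(n) (seq_len(n) - (n + 1) / 2) / (n / 2)
  X <- array(rep(u(nx), times = ny * nz), dim)
  Y <- array(rep(rep(u(ny), each = nx), times = nz), dim)
  Z <- array(rep(u(nz), each = nx * ny), dim)
  ell <- function(cx, cy, cz, rx, ry, rz)
    ((X - cx) / rx)^2 + ((Y - cy) / ry)^2 + ((Z - cz) / rz)^2 <= 1
  lab <- array(0L, dim)
  brain <- ell(0, 0.03, 0, 0.88, 0.92, 0.85)
  inner <- ell(0, 0.03, 0, 0.66, 0.72, 0.62)
  lab[brain] <- 1L                       # cortex shell
  lab[inner] <- 2L                       # white matter
  cereb <- brain & (Z < -0.45) & (Y < -0.25)
  lab[cereb] <- 6L                       # cerebellum
  lab[ell(0, -0.08, -0.02, 0.20, 0.16, 0.16)] <- 3L   # thalamus
  lab[ell(0.28, 0.18, 0.12, 0.12, 0.12, 0.12) |
      ell(-0.28, 0.18, 0.12, 0.12, 0.12, 0.12)] <- 4L # caudate
  lab[ell(0.44, 0.02, 0, 0.14, 0.14, 0.14) |
      ell(-0.44, 0.02, 0, 0.14, 0.14, 0.14)] <- 5L    # putamen
  region_map(lab, voxel_size,
             c(`1` = "cortex", `2` = "white_matter", `3` = "thalamus",
               `4` = "caudate", `5` = "putamen", `6` = "cerebellum"))
}

#' Default kinetic ground truth for the brain phantom
#'
#' Regional (K1, k2) values spanning K1 0.05-0.3 mL cm^-3 min^-1 and k2
#' 0.02-0.15 min^-1, giving distinct VT contrast between gray- and
#' white-matter-like regions.
#'
#' @return A \code{\link{kinetic_truth}} for labels 1-6.
#' @export
brain_kinetic_truth <- function() {
  kinetic_truth(
    K1 = c(`1` = 0.28, `2` = 0.09, `3` = 0.25, `4` = 0.21, `5` = 0.26,
           `6` = 0.30),
    k2 = c(`1` = 0.040, `2` = 0.055, `3` = 0.046, `4` = 0.052, `5` = 0.057,
           `6` = 0.065))
}

#' Render a noise-free dynamic phantom
#'
#' Each region's voxels carry that region's one-tissue-compartment TAC; an
#' optional isotropic Gaussian blur of the stated FWHM (approximating the
#' reconstructed resolution of ~3 mm) is applied per frame.  Background stays
#' zero before the blur.
#'
#' @param regions a \code{\link{region_map}}.
#' @param truth a \code{\link{kinetic_truth}} covering every nonzero label.
#' @param aif an \code{\link{input_function}}.
#' @param schedule a \code{\link{frame_schedule}}.
#' @param psf_fwhm point-spread FWHM in mm (0 disables the blur).
#' @return A \code{\link{dynamic_image}} with attribute \code{"tacs"} holding
#'   the noise-free regional TAC matrix (frames x regions).
#' @export
render_phantom <- function(regions, truth, aif, schedule, psf_fwhm = 3) {
  labs <- sort(unique(as.vector(regions$labels[regions$labels > 0])))
  missing <- setdiff(as.character(labs), names(truth$K1))
  if (length(missing))
    stop_badarg("no kinetic parameters for label(s): ",
                paste(missing, collapse = ", "))
  nf <- length(schedule)
  tacs <- sapply(as.character(labs), function(l)
    tissue_tac(truth$K1[[l]], truth$k2[[l]], aif, schedule))
  d <- dim(regions$labels)
  arr <- array(0, c(d, nf))
  for (j in seq_along(labs)) {
    idx <- which(regions$labels == labs[j])
    for (i in seq_len(nf))
      arr[idx + (i - 1) * prod(d)] <- tacs[i, j]
  }
  img <- dynamic_image(arr, schedule, regions$voxel_size)
  if (psf_fwhm > 0)
    img <- map_frames(img, function(fr, i)
      gaussian_filter_fwhm(fr, psf_fwhm, regions$voxel_size))
  attr(img, "tacs") <- tacs
  img
}
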