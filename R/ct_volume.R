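#' CT volume container
#'
#' A minimal container for CT image data calibrated in Hounsfield units
#' (HU).  Voxels are stored as a numeric array with dimensions
#' `(rows, cols, slices)`; a plain matrix is accepted and treated as a
#' single slice.  In-plane index order is `(row, col)` everywhere in the
#' package; area and volume computations depend only on the physical
#' spacing, not on patient orientation.
#'
#' @param voxels numeric array `(rows, cols, slices)` or matrix
#'   `(rows, cols)` of HU values in `[-1024, 3071]`.
#' @param pixel_spacing length-2 numeric, mm per pixel as `(row, col)`.
#' @param slice_thickness slice thickness in mm.
#' @param slice_locations optional numeric vector of slice positions (mm),
#'   one per slice.
#'
#' @return An object of class `ct_volume` with elements `voxels`,
#'   `pixel_spacing`, `slice_thickness` and `slice_locations`.
#' @examples
#' vol <- ct_volume(matrix(-1000, 16, 16), pixel_spacing = c(0.8, 0.8))
#' dim(vol$voxels)
#' @export
ct_volume <- function(voxels, pixel_spacing, slice_thickness = 1,
                      slice_locations = NULL) {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop2("voxels must be a matrix or a (rows, cols, slices) array")
  d <- dim(voxels)
  if (d[1] < 8L || d[2] < 8L)
    stop2("in-plane grid must be at least 8x8, got ", d[1], "x", d[2])
  rng <- range(voxels)
  if (rng[1] < -1024 || rng[2] > 3071)
    stop2("voxel values must lie in [-1024, 3071] HU; observed range [",
          rng[1], ", ", rng[2], "]")
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) != 2L || any(!is.finite(pixel_spacing)) ||
      any(pixel_spacing <= 0))
    stop2("pixel_spacing must be two positive mm values (row, col)")
  if (!is.finite(slice_thickness) || slice_thickness <= 0)
    stop2("slice_thickness must be positive")
  if (!is.null(slice_locations) && length(slice_locations) != d[3])
    stop2("slice_locations must have one entry per slice")
  structure(
    list(voxels = voxels, pixel_spacing = pixel_spacing,
         slice_thickness = slice_thickness,
         slice_locations = slice_locations),
    class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<ct_volume> %d x %d pixels, %d slice(s); spacing %.3g x %.3g mm, thickness %.3g mm\n",
    d[1], d[2], d[3], x$pixel_spacing[1], x$pixel_spacing[2],
    x$slice_thickness))
  cat(sprintf("  HU range [%g, %g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Extract one axial slice as a matrix
#'
#' @param volume a [ct_volume].
#' @param slice slice index (1-based).
#' @return numeric matrix `(rows, cols)` of HU values.
#' @export
get_slice <- function(volume, slice = 1L) {
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume$voxels)
  if (slice < 1L || slice > d[3]) stop2("slice index out of range")
  volume$voxels[, , slice]
}

# In-plane pixel area in cm^2.
pixel_area_cm2 <- function(volume) {
  prod(volume$pixel_spacing) / 100
}

# Label connected components of a logical mask (matrix or 3-D array);
# 4-connectivity in-plane, face connectivity across slices.
label_components <- function(mask) {
  d <- dim(mask)
  if (is.null(d)) stop2("mask must be a matrix or array")
  labels <- label_components_cpp(as.logical(mask), as.integer(d))
  out <- array(labels, dim = d)
  attr(out, "n_components") <- attr(labels, "n_components")
  out
}
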