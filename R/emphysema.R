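# Emphysema quantification: threshold lung segmentation and the
# low-attenuation-area (LAA) fraction below -950 HU.

#' Segment the lung fields by thresholding
#'
#' Thresholds the volume at `lung_threshold` (default -400 HU), labels
#' connected components (4-connectivity in-plane, face connectivity
#' across slices), discards every component touching the image border
#' (exterior air), and keeps the two largest remaining components - or
#' one, if only one interior air-like component exists.
#'
#' @param volume a [ct_volume].
#' @param lung_threshold HU; voxels strictly below it are lung
#'   candidates.
#' @return logical array, `TRUE` inside the lung mask.
#' @examples
#' ph <- make_phantom(phantom_config(seed = 3))
#' mask <- segment_lungs(ph$volume)
#' sum(mask) == ph$truth$n_lung_pixels
#' @export
segment_lungs <- function(volume, lung_threshold = -400) {
  stopifnot(inherits(volume, "ct_volume"))
  cand <- volume$voxels < lung_threshold
  comp <- label_components(cand)
  d <- dim(comp)
  border <- unique(c(
    comp[c(1, d[1]), , ], comp[, c(1, d[2]), , drop = FALSE]))
  border <- setdiff(border, 0L)
  sizes <- tabulate(comp[comp > 0L], nbins = attr(comp, "n_components"))
  interior <- setdiff(which(sizes > 0), border)
  if (length(interior) == 0)
    stop2("no interior air-like component below ", lung_threshold,
          " HU; the volume does not contain enclosed lung fields")
  keep <- interior[order(sizes[interior], decreasing = TRUE)]
  keep <- keep[seq_len(min(2L, length(keep)))]
  array(comp %in% keep, dim = d)
}

#' Low-attenuation-area fraction of the lung
#'
#' Counts lung voxels strictly below `threshold` (default -950 HU) and
#' reports them as a fraction of all lung voxels - the standard CT
#' emphysema index.  The statistic is a pure voxel histogram: it is
#' invariant to any permutation of voxels inside the mask and monotone
#' nonincreasing in the threshold.
#'
#' @param volume a [ct_volume].
#' @param lung_mask logical array from [segment_lungs()] (or any mask of
#'   the same dimensions).
#' @param threshold HU; strict inequality, matching the "less than -950
#'   HU" definition.
#' @return An `emphysema_result` list: `laa_fraction`, `lung_voxels`,
#'   `laa_voxels`, `threshold`.
#' @examples
#' ph <- make_phantom(phantom_config(laa_fraction = 0.2, seed = 4))
#' res <- compute_laa(ph$volume, segment_lungs(ph$volume))
#' res$laa_fraction
#' @export
compute_laa <- function(volume, lung_mask, threshold = -950) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!identical(dim(lung_mask), dim(volume$voxels)))
    stop2("lung_mask dimensions do not match the volume")
  n_lung <- sum(lung_mask)
  if (n_lung == 0) stop2("empty lung mask")
  n_laa <- sum(volume$voxels[lung_mask] < threshold)
  structure(list(laa_fraction = n_laa / n_lung,
                 lung_voxels = as.integer(n_lung),
                 laa_voxels = as.integer(n_laa),
                 threshold = threshold),
            class = "emphysema_result")
}
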