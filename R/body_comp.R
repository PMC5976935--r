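# Body composition at the user-designated T3-level slice: pectoralis
# muscle segmentation with seeded mediastinum exclusion, muscle area and
# attenuation, and subcutaneous fat attenuation in the -120..-60 HU
# window.

.slice_of <- function(x, slice_index = 1L) {
  if (inherits(x, "ct_volume")) get_slice(x, slice_index) else as.matrix(x)
}

#' Segment the pectoralis muscle with seeded mediastinum exclusion
#'
#' Thresholds the slice by the skeletal-muscle HU window (default
#' `[-29, 150]`), labels 4-connected components, removes the component
#' containing the user-supplied mediastinum seed (the mouse click of the
#' original semi-automatic workflow), and returns the remaining
#' components as the pectoralis mask.  A seed that misses in-window
#' tissue is an error; a slice with no in-window pixels at all yields an
#' empty mask with a warning.
#'
#' @param slice single-slice [ct_volume] or HU matrix (the T3-level
#'   slice, chosen by the user).
#' @param mediastinum_seed `(row, col)` pixel inside mediastinal soft
#'   tissue.
#' @param muscle_window length-2 HU window (inclusive).
#' @param slice_index slice to use when `slice` is a multi-slice volume.
#' @return logical matrix, `TRUE` on pectoralis pixels.
#' @examples
#' ph <- make_phantom(phantom_config(seed = 5))
#' mask <- segment_pectoralis(ph$volume, ph$truth$mediastinum_seed)
#' sum(mask) == ph$truth$n_muscle_pixels
#' @export
segment_pectoralis <- function(slice, mediastinum_seed,
                               muscle_window = c(-29, 150),
                               slice_index = 1L) {
  m <- .slice_of(slice, slice_index)
  nr <- nrow(m); nc <- ncol(m)
  seed <- as.integer(round(mediastinum_seed))
  if (seed[1] < 1 || seed[1] > nr || seed[2] < 1 || seed[2] > nc)
    stop2("mediastinum seed (", seed[1], ",", seed[2],
          ") lies outside the ", nr, "x", nc, " grid")
  in_window <- m >= muscle_window[1] & m <= muscle_window[2]
  if (!any(in_window)) {
    warn2("no pixels inside the muscle HU window [", muscle_window[1],
          ", ", muscle_window[2], "]; returning an empty mask")
    return(matrix(FALSE, nr, nc))
  }
  comp <- label_components(in_window)
  seed_comp <- comp[seed[1], seed[2]]
  if (seed_comp == 0L)
    stop2("mediastinum seed does not hit tissue inside the muscle ",
          "window; place the seed on mediastinal soft tissue")
  matrix(comp != 0L & comp != seed_comp, nr, nc)
}

#' Muscle area and mean attenuation
#'
#' Area is pixel count times the in-plane pixel area, reported in cm^2
#' (`pixels x row_spacing x col_spacing / 100`); mean attenuation is the
#' arithmetic mean HU over the mask.  An empty mask gives area 0 and a
#' missing mean.
#'
#' @param slice single-slice [ct_volume] or HU matrix.
#' @param muscle_mask logical matrix from [segment_pectoralis()].
#' @param pixel_spacing mm `(row, col)`; taken from the volume when
#'   `slice` is a [ct_volume].
#' @param slice_index slice to use for a multi-slice volume.
#' @return list with `muscle_area_cm2`, `muscle_mean_hu`,
#'   `muscle_pixels`.
#' @export
muscle_metrics <- function(slice, muscle_mask, pixel_spacing = NULL,
                           slice_index = 1L) {
  m <- .slice_of(slice, slice_index)
  if (is.null(pixel_spacing)) {
    if (!inherits(slice, "ct_volume"))
      stop2("pixel_spacing is required when slice is a bare matrix")
    pixel_spacing <- slice$pixel_spacing
  }
  if (!identical(dim(muscle_mask), dim(m)))
    stop2("muscle_mask dimensions do not match the slice")
  n <- sum(muscle_mask)
  list(muscle_area_cm2 = n * prod(pixel_spacing) / 100,
       muscle_mean_hu = if (n > 0) mean(m[muscle_mask]) else NA_real_,
       muscle_pixels = as.integer(n))
}

#' Segment the body outline
#'
#' Pixels at or above `body_threshold` (default -500 HU), keeping the
#' largest component that does not touch the image border.  Used as the
#' search region for subcutaneous fat.
#'
#' @param slice single-slice [ct_volume] or HU matrix.
#' @param body_threshold HU.
#' @param slice_index slice to use for a multi-slice volume.
#' @return logical matrix.
#' @export
segment_body <- function(slice, body_threshold = -500, slice_index = 1L) {
  m <- .slice_of(slice, slice_index)
  cand <- m >= body_threshold
  comp <- label_components(cand)
  d <- dim(comp)
  border <- setdiff(unique(c(comp[c(1, d[1]), ], comp[, c(1, d[2])])), 0L)
  sizes <- tabulate(comp[comp > 0L], nbins = attr(comp, "n_components"))
  interior <- setdiff(which(sizes > 0), border)
  if (length(interior) == 0)
    stop2("no border-free body component at or above ", body_threshold,
          " HU")
  keep <- interior[which.max(sizes[interior])]
  matrix(comp == keep, d[1], d[2])
}

#' Segment subcutaneous fat by attenuation window
#'
#' Fat pixels are body pixels with HU inside `fat_window`
#' (default `[-120, -60]`) that belong neither to the lung fields nor to
#' the muscle-window components (pectoralis and mediastinum/heart).  On
#' phantoms this recovers the painted fat ring exactly; on real slices
#' the window plus exclusion rule approximates the subcutaneous
#' compartment.
#'
#' @param slice single-slice [ct_volume] or HU matrix.
#' @param body_mask optional logical matrix from [segment_body()];
#'   computed internally when `NULL`.
#' @param fat_window length-2 HU window (inclusive).
#' @param muscle_window HU window used to exclude soft-tissue components.
#' @param lung_threshold HU used to exclude intra-lung pixels.
#' @param slice_index slice to use for a multi-slice volume.
#' @return logical matrix, `TRUE` on fat pixels.
#' @examples
#' ph <- make_phantom(phantom_config(seed = 6))
#' fm <- segment_subcutaneous_fat(ph$volume)
#' sum(fm) == ph$truth$n_fat_pixels
#' @export
segment_subcutaneous_fat <- function(slice, body_mask = NULL,
                                     fat_window = c(-120, -60),
                                     muscle_window = c(-29, 150),
                                     lung_threshold = -400,
                                     slice_index = 1L) {
  m <- .slice_of(slice, slice_index)
  if (is.null(body_mask)) body_mask <- segment_body(m, slice_index = 1L)
  if (!identical(dim(body_mask), dim(m)))
    stop2("body_mask dimensions do not match the slice")
  if (!any(body_mask)) stop2("empty body mask")
  fat <- body_mask & m >= fat_window[1] & m <= fat_window[2]
  # exclude anything inside lung components (holes in the body mask are
  # not part of body_mask, but guard against in-window pixels inside
  # lung regions of the full slice)
  lung_like <- m < lung_threshold
  lung_comp <- label_components(lung_like)
  d <- dim(lung_comp)
  border <- setdiff(unique(c(lung_comp[c(1, d[1]), ],
                             lung_comp[, c(1, d[2])])), 0L)
  interior_lung <- lung_comp != 0L &
    !(lung_comp %in% border)
  fat <- fat & !matrix(interior_lung, nrow(m), ncol(m))
  fat[m >= muscle_window[1] & m <= muscle_window[2]] <- FALSE
  if (!any(fat))
    warn2("no pixels inside the fat window [", fat_window[1], ", ",
          fat_window[2], "]; returning an empty mask")
  fat
}

#' Mean fat attenuation
#'
#' Arithmetic mean HU over the fat mask; `NA` with a warning when the
#' mask is empty.
#'
#' @param slice single-slice [ct_volume] or HU matrix.
#' @param fat_mask logical matrix from [segment_subcutaneous_fat()].
#' @param slice_index slice to use for a multi-slice volume.
#' @return mean HU (scalar).
#' @export
fat_attenuation <- function(slice, fat_mask, slice_index = 1L) {
  m <- .slice_of(slice, slice_index)
  if (!identical(dim(fat_mask), dim(m)))
    stop2("fat_mask dimensions do not match the slice")
  if (!any(fat_mask)) {
    warn2("empty fat mask; mean fat attenuation is missing")
    return(NA_real_)
  }
  mean(m[fat_mask])
}

#' Full body-composition measurement of one slice
#'
#' Runs pectoralis segmentation, muscle metrics, fat segmentation and
#' fat attenuation in one call.
#'
#' @inheritParams segment_pectoralis
#' @inheritParams segment_subcutaneous_fat
#' @return A `body_comp_result` list: `muscle_area_cm2`,
#'   `muscle_mean_hu`, `fat_mean_hu`, `muscle_pixels`, `fat_pixels`.
#' @export
body_composition <- function(slice, mediastinum_seed,
                             muscle_window = c(-29, 150),
                             fat_window = c(-120, -60),
                             slice_index = 1L) {
  stopifnot(inherits(slice, "ct_volume"))
  mask <- segment_pectoralis(slice, mediastinum_seed, muscle_window,
                             slice_index)
  mm <- muscle_metrics(slice, mask, slice_index = slice_index)
  fm <- segment_subcutaneous_fat(slice, muscle_window = muscle_window,
                                 fat_window = fat_window,
                                 slice_index = slice_index)
  structure(list(muscle_area_cm2 = mm$muscle_area_cm2,
                 muscle_mean_hu = mm$muscle_mean_hu,
                 fat_mean_hu = fat_attenuation(slice, fm, slice_index),
                 muscle_pixels = mm$muscle_pixels,
                 fat_pixels = as.integer(sum(fm))),
            class = "body_comp_result")
}
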