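# Coronary artery calcification (CAC) scoring: background normalisation,
# 130 HU threshold pixel counting inside a circular heart ROI, heuristic
# grade calibration against reader grades, and reader agreement.

#' Normalise a slice against its background air level
#'
#' Estimates the background air level as the median of all pixels below
#' -800 HU and subtracts the difference from -1000 HU off the whole
#' slice, so that a uniformly offset acquisition is restored to the
#' calibrated HU scale before thresholding.  At least 1% of pixels must
#' be air-like; otherwise the caller is told to skip normalisation
#' explicitly rather than silently proceeding.
#'
#' @param slice a single-slice [ct_volume] (or a volume, normalised as a
#'   whole) containing exterior air.
#' @return list with `volume` (normalised) and `offset` (HU subtracted).
#' @examples
#' ph <- make_phantom(phantom_config(background_offset = 15))
#' normalize_background(ph$volume)$offset
#' @export
normalize_background <- function(slice) {
  stopifnot(inherits(slice, "ct_volume"))
  air <- slice$voxels[slice$voxels < -800]
  if (length(air) < 0.01 * length(slice$voxels))
    stop2("fewer than 1% of pixels are below -800 HU; no usable air ",
          "background - skip normalization explicitly if intended")
  offset <- median(air) - (-1000)
  out <- slice
  out$voxels <- pmin(pmax(slice$voxels - offset, -1024), 3071)
  list(volume = out, offset = offset)
}

#' Count calcified pixels inside a circular heart ROI
#'
#' Counts pixels strictly above `threshold` (130 HU by default, the
#' standard calcium detection threshold) whose centres lie within the
#' circle of `roi_radius` pixels around `roi_center`.  The ROI must lie
#' fully inside the image grid.
#'
#' @param slice single-slice [ct_volume] or matrix of HU values.
#' @param roi_center `(row, col)` pixel coordinates of the circle centre.
#' @param roi_radius circle radius in pixels.
#' @param threshold HU threshold; pixels must exceed it strictly.
#' @param slice_index which slice of a multi-slice volume to use.
#' @return integer pixel count.
#' @examples
#' ph <- make_phantom(phantom_config(seed = 2))
#' count_calcified_pixels(ph$volume, ph$truth$heart_center,
#'                        ph$truth$heart_radius)
#' ph$truth$calcified_pixel_count
#' @export
count_calcified_pixels <- function(slice, roi_center, roi_radius,
                                   threshold = 130, slice_index = 1L) {
  m <- if (inherits(slice, "ct_volume")) get_slice(slice, slice_index)
       else as.matrix(slice)
  nr <- nrow(m); nc <- ncol(m)
  if (roi_center[1] - roi_radius < 1 || roi_center[1] + roi_radius > nr ||
      roi_center[2] - roi_radius < 1 || roi_center[2] + roi_radius > nc)
    stop2("circular ROI (center ", roi_center[1], ",", roi_center[2],
          ", radius ", roi_radius, ") extends outside the ", nr, "x", nc,
          " grid")
  roi <- .disk_mask(nr, nc, roi_center, roi_radius)
  sum(m[roi] > threshold)
}

#' Grade cutpoints for the four-grade CAC scale
#'
#' Three strictly increasing pixel-count thresholds `c1 < c2 < c3`
#' separating grades 0 (none), 1 (minimal), 2 (moderate), 3 (severe).
#'
#' @param c1,c2,c3 increasing nonnegative counts.
#' @return A `grade_cutpoints` object.
#' @export
grade_cutpoints <- function(c1, c2, c3) {
  if (!(0 <= c1 && c1 < c2 && c2 < c3))
    stop2("cutpoints must satisfy 0 <= c1 < c2 < c3")
  structure(list(c1 = c1, c2 = c2, c3 = c3), class = "grade_cutpoints")
}

#' Calibrate grade cutpoints from reader reference grades
#'
#' Chooses cutpoints by quantile matching: the cutpoint separating grades
#' below `k` from grade `k` and above sits at the count quantile equal to
#' the cumulative reference-grade frequency of grades `< k`, realised as
#' the midpoint between the two sorted counts straddling that boundary.
#' This reproduces the readers' grade marginal distribution on the
#' calibration set (within ties).
#'
#' @param counts calcified-pixel counts, one per calibration subject.
#' @param reference_grades integer reader grades in `0:3`, same length.
#' @return A [grade_cutpoints()] object.
#' @examples
#' calibrate_cutpoints(c(0, 0, 10, 10, 100, 100, 1000, 1000),
#'                     c(0, 0, 1, 1, 2, 2, 3, 3))
#' @export
calibrate_cutpoints <- function(counts, reference_grades) {
  if (length(counts) != length(reference_grades))
    stop2("counts and reference_grades must have equal length")
  g <- as.integer(reference_grades)
  if (any(is.na(g)) || any(g < 0 | g > 3))
    stop2("reference grades must be integers in 0..3")
  if (length(unique(g)) < 2)
    stop2("degenerate reference: only one grade present")
  missing_g <- setdiff(0:3, unique(g))
  if (length(missing_g) > 0)
    stop2("reference must contain every grade; missing: ",
          paste(missing_g, collapse = ", "))
  s <- sort(counts)
  n <- length(s)
  cp <- vapply(1:3, function(k) {
    m <- sum(g < k)                      # boundary position in sorted counts
    (s[m] + s[m + 1]) / 2
  }, numeric(1))
  if (!(cp[1] < cp[2] && cp[2] < cp[3]))
    stop2("reference grades are not separable into strictly increasing ",
          "cutpoints (tied counts across grade boundaries)")
  grade_cutpoints(cp[1], cp[2], cp[3])
}

#' Map a calcified-pixel count to a CAC grade
#'
#' Grade = number of cutpoints less than or equal to the count: a count
#' equal to a cutpoint takes the higher grade (frozen boundary rule).
#' Grades use the 0-3 coding (0 none, 1 minimal, 2 moderate, 3 severe);
#' use [cac_grade_labels()] for printable labels.
#'
#' @param pixel_count integer count(s) of calcified pixels.
#' @param cutpoints a [grade_cutpoints()] object.
#' @return integer grade(s) in `0:3`.
#' @export
assign_grade <- function(pixel_count, cutpoints) {
  stopifnot(inherits(cutpoints, "grade_cutpoints"))
  cp <- unlist(cutpoints)
  vapply(pixel_count, function(x) as.integer(sum(cp <= x)), integer(1))
}

#' Labels for the four CAC grades
#'
#' @return character vector `c("none", "minimal", "moderate", "severe")`
#'   named by the 0-3 grade codes.
#' @export
cac_grade_labels <- function() {
  c(`0` = "none", `1` = "minimal", `2` = "moderate", `3` = "severe")
}

#' Agreement between two sets of CAC grades
#'
#' Squared Pearson correlation between two grade vectors, the statistic
#' used to compare program grades against reader grades.
#'
#' @param grades_a,grades_b equal-length numeric vectors, each with at
#'   least 3 observations and nonzero variance.
#' @return r-squared in `[0, 1]`.
#' @export
grade_agreement <- function(grades_a, grades_b) {
  if (length(grades_a) != length(grades_b))
    stop2("grade vectors must have equal length")
  if (length(grades_a) < 3)
    stop2("need at least 3 observations to assess agreement")
  if (var(grades_a) == 0 || var(grades_b) == 0)
    stop2("grade agreement undefined: zero variance in a grade vector")
  stats::cor(grades_a, grades_b)^2
}

#' Score CAC on a slice in one call
#'
#' Convenience wrapper: optional background normalisation, threshold
#' pixel counting in the heart ROI, and (if cutpoints are supplied) grade
#' assignment.
#'
#' @inheritParams count_calcified_pixels
#' @param cutpoints optional [grade_cutpoints()].
#' @param normalize whether to run [normalize_background()] first.
#' @return A `cac_result` list: `pixel_count`, `grade` (NA without
#'   cutpoints), `grade_label`, `roi_center`, `roi_radius`,
#'   `normalization_offset`.
#' @export
cac_score <- function(slice, roi_center, roi_radius, threshold = 130,
                      cutpoints = NULL, normalize = TRUE,
                      slice_index = 1L) {
  offset <- 0
  if (normalize) {
    nb <- normalize_background(slice)
    slice <- nb$volume
    offset <- nb$offset
  }
  count <- count_calcified_pixels(slice, roi_center, roi_radius,
                                  threshold, slice_index)
  grade <- if (!is.null(cutpoints)) assign_grade(count, cutpoints)
           else NA_integer_
  structure(list(pixel_count = count, grade = grade,
                 grade_label = if (!is.na(grade))
                   unname(cac_grade_labels()[as.character(grade)])
                 else NA_character_,
                 roi_center = roi_center, roi_radius = roi_radius,
                 normalization_offset = offset),
            class = "cac_result")
}
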