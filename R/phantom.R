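# Synthetic thorax phantoms.  The slice layout (anterior at row 1):
# air background, body outline filled with subcutaneous/anterior fat,
# two pectoralis compartments, two lung fields with scattered
# low-attenuation pixels, a heart disk carrying hyperdense plaques, and a
# mediastinal soft-tissue bridge that is inside the muscle HU window but
# spatially disjoint from the pectoralis compartments (so that seeded
# mediastinum removal is exercised).  Every ground-truth value is
# enumerated from the painted label mask, never taken from the config.

.lab <- c(air = 0L, fat = 1L, muscle = 2L, lung = 3L, laa = 4L,
          heart = 5L, plaque = 6L, mediastinum = 7L)

#' Phantom configuration
#'
#' Defaults paint a 160 x 160 single-slice thorax at 0.8 mm pixels:
#' lungs at -850 HU with a 13% low-attenuation-area target at -980 HU,
#' fat ring drawn from a clipped normal centred at -92.5 HU (sd 4.4),
#' pectoralis muscle at 57 HU, heart at 35 HU carrying four 300-800 HU
#' plaques.  These levels mirror the descriptive scale of a screening
#' cohort (muscle ~57 HU, fat ~-92 HU, emphysema fraction ~0.13).
#'
#' @param grid in-plane grid size `(rows, cols)`, minimum 64.
#' @param n_slices number of identical slices (1 = single axial slice).
#' @param pixel_spacing mm per pixel `(row, col)`.
#' @param slice_thickness mm.
#' @param background_hu air level, normally -1000 HU.
#' @param background_offset uniform HU offset added to every pixel after
#'   painting; exercises background normalisation.  Default 0 (off).
#' @param fat_mean_hu,fat_sd_hu fat attenuation distribution, clipped to
#'   the -120..-60 HU fat window.
#' @param muscle_hu,muscle_sd_hu pectoralis attenuation (sd 0 = uniform).
#' @param lung_hu,laa_hu,laa_fraction lung parenchyma level, the level
#'   painted into low-attenuation pixels, and the target LAA fraction.
#' @param heart_hu,mediastinum_hu soft-tissue levels.
#' @param n_plaques,plaque_radius,plaque_hu_range calcified plaques: how
#'   many disks, their radius in pixels, and the HU range they are drawn
#'   from (uniform per plaque).
#' @param seed integer; fixes all randomness in the phantom.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid = c(160, 160), n_slices = 1L,
                           pixel_spacing = c(0.8, 0.8),
                           slice_thickness = 2.5,
                           background_hu = -1000, background_offset = 0,
                           fat_mean_hu = -92.5, fat_sd_hu = 4.4,
                           muscle_hu = 57, muscle_sd_hu = 0,
                           lung_hu = -850, laa_hu = -980,
                           laa_fraction = 0.13,
                           heart_hu = 35, mediastinum_hu = 40,
                           n_plaques = 4L, plaque_radius = 2L,
                           plaque_hu_range = c(300, 800),
                           seed = 1L) {
  cfg <- list(grid = as.integer(grid), n_slices = as.integer(n_slices),
              pixel_spacing = pixel_spacing,
              slice_thickness = slice_thickness,
              background_hu = background_hu,
              background_offset = background_offset,
              fat_mean_hu = fat_mean_hu, fat_sd_hu = fat_sd_hu,
              muscle_hu = muscle_hu, muscle_sd_hu = muscle_sd_hu,
              lung_hu = lung_hu, laa_hu = laa_hu,
              laa_fraction = laa_fraction,
              heart_hu = heart_hu, mediastinum_hu = mediastinum_hu,
              n_plaques = as.integer(n_plaques),
              plaque_radius = as.integer(plaque_radius),
              plaque_hu_range = plaque_hu_range, seed = as.integer(seed))
  hu_vals <- c(cfg$background_hu, cfg$fat_mean_hu, cfg$muscle_hu,
               cfg$lung_hu, cfg$laa_hu, cfg$heart_hu, cfg$mediastinum_hu,
               cfg$plaque_hu_range)
  if (any(hu_vals < -1024 | hu_vals > 3071))
    stop2("all configured HU levels must lie in [-1024, 3071]")
  if (cfg$laa_fraction < 0 || cfg$laa_fraction > 1)
    stop2("laa_fraction must be in [0, 1]")
  class(cfg) <- "phantom_config"
  cfg
}

# Pixel-centre membership of an ellipse; the same <=1 rule is used for
# painting and for the circular ROI, so counts agree exactly.
.ellipse_mask <- function(nr, nc, center, semi) {
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((r - center[1]) / semi[1])^2 + ((c - center[2]) / semi[2])^2 <= 1
}

.disk_mask <- function(nr, nc, center, radius) {
  .ellipse_mask(nr, nc, center, c(radius, radius))
}

#' Generate a thorax phantom with enumerated ground truth
#'
#' Paints the phantom described by `config` and returns the HU volume
#' together with a `phantom_truth` list whose every field is recomputed by
#' direct enumeration of the painted label masks.  Painted regions are
#' pairwise disjoint by construction (one label per pixel) and the
#' mediastinal bridge is verified to be 4-disjoint from the pectoralis
#' compartments.
#'
#' @param config a [phantom_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{volume}{[ct_volume] in HU (including any background offset).}
#'     \item{truth}{`phantom_truth`: `calcified_pixel_count`,
#'       `true_laa_fraction`, `true_muscle_area_cm2`,
#'       `true_muscle_mean_hu`, `true_fat_mean_hu`, `heart_center`,
#'       `heart_radius`, `mediastinum_seed`, plus pixel tallies.}
#'     \item{labels}{integer array of region labels (see
#'       `attr(labels, "legend")`).}
#'   }
#' @examples
#' ph <- make_phantom(phantom_config(seed = 7))
#' ph$truth$true_laa_fraction
#' @export
make_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  nr <- config$grid[1]; nc <- config$grid[2]
  if (nr < 64 || nc < 64)
    stop2("phantom regions cannot fit a grid smaller than 64x64")

  with_seed(config$seed, {
    lab <- matrix(.lab[["air"]], nr, nc)
    body <- .ellipse_mask(nr, nc, c(0.55 * nr, 0.50 * nc),
                          c(0.40 * nr, 0.44 * nc))
    lab[body] <- .lab[["fat"]]

    musc_l <- .ellipse_mask(nr, nc, c(0.30 * nr, 0.32 * nc),
                            c(0.055 * nr, 0.11 * nc))
    musc_r <- .ellipse_mask(nr, nc, c(0.30 * nr, 0.68 * nc),
                            c(0.055 * nr, 0.11 * nc))
    lab[(musc_l | musc_r) & body] <- .lab[["muscle"]]

    lung_l <- .ellipse_mask(nr, nc, c(0.58 * nr, 0.30 * nc),
                            c(0.22 * nr, 0.11 * nc))
    lung_r <- .ellipse_mask(nr, nc, c(0.58 * nr, 0.70 * nc),
                            c(0.22 * nr, 0.11 * nc))
    lab[(lung_l | lung_r) & body] <- .lab[["lung"]]

    heart_center <- c(round(0.62 * nr), round(0.50 * nc))
    heart_radius <- round(0.08 * nr)
    heart <- .disk_mask(nr, nc, heart_center, heart_radius)
    if (any(heart & (lung_l | lung_r)))
      stop2("phantom regions cannot fit: heart overlaps a lung field")
    lab[heart & body] <- .lab[["heart"]]

    med_rows <- seq(round(0.40 * nr), round(0.62 * nr))
    med_cols <- seq(round(0.47 * nc), round(0.53 * nc))
    med <- matrix(FALSE, nr, nc)
    med[med_rows, med_cols] <- TRUE
    med <- med & body & !heart & !(lung_l | lung_r)
    lab[med] <- .lab[["mediastinum"]]

    # plaques on a deterministic ring at half the heart radius
    if (config$n_plaques > 0) {
      ang <- 2 * pi * (seq_len(config$n_plaques) - 1) / config$n_plaques
      for (p in seq_len(config$n_plaques)) {
        ctr <- heart_center + 0.5 * heart_radius * c(sin(ang[p]), cos(ang[p]))
        pl <- .disk_mask(nr, nc, ctr, config$plaque_radius)
        if (any(pl & !heart))
          stop2("phantom regions cannot fit: plaque leaves the heart disk")
        lab[pl] <- .lab[["plaque"]]
      }
    }

    # low-attenuation pixels: a seeded sample of lung pixels sized to the
    # closest achievable count for the target fraction
    lung_idx <- which(lab == .lab[["lung"]])
    n_lung <- length(lung_idx)
    if (n_lung == 0) stop2("phantom regions cannot fit: no lung pixels")
    k <- round(config$laa_fraction * n_lung)
    if (k > 0) lab[sample(lung_idx, k)] <- .lab[["laa"]]

    # guard: mediastinum/heart must not be 4-adjacent to pectoralis
    in_window <- lab %in% c(.lab[["muscle"]], .lab[["heart"]],
                            .lab[["plaque"]], .lab[["mediastinum"]])
    comp <- label_components(matrix(in_window, nr, nc))
    musc_comps <- unique(comp[lab == .lab[["muscle"]]])
    med_comps <- unique(comp[lab %in% c(.lab[["heart"]],
                                        .lab[["mediastinum"]])])
    if (length(intersect(musc_comps, med_comps)) > 0)
      stop2("phantom regions cannot fit: mediastinum touches pectoralis")

    hu <- matrix(NA_real_, nr, nc)
    hu[lab == .lab[["air"]]] <- config$background_hu
    fat_idx <- which(lab == .lab[["fat"]])
    hu[fat_idx] <- pmin(pmax(
      rnorm(length(fat_idx), config$fat_mean_hu, config$fat_sd_hu),
      -120), -60)
    musc_idx <- which(lab == .lab[["muscle"]])
    hu[musc_idx] <- if (config$muscle_sd_hu > 0)
      rnorm(length(musc_idx), config$muscle_hu, config$muscle_sd_hu)
    else config$muscle_hu
    hu[lab == .lab[["lung"]]] <- config$lung_hu
    hu[lab == .lab[["laa"]]] <- config$laa_hu
    hu[lab == .lab[["heart"]]] <- config$heart_hu
    hu[lab == .lab[["mediastinum"]]] <- config$mediastinum_hu
    if (config$n_plaques > 0) {
      plaque_hu <- runif(config$n_plaques, config$plaque_hu_range[1],
                         config$plaque_hu_range[2])
      # repaint plaque disks so each carries its own uniform level
      for (p in seq_len(config$n_plaques)) {
        ang_p <- 2 * pi * (p - 1) / config$n_plaques
        ctr <- heart_center + 0.5 * heart_radius *
          c(sin(ang_p), cos(ang_p))
        pl <- .disk_mask(nr, nc, ctr, config$plaque_radius)
        hu[pl & lab == .lab[["plaque"]]] <- plaque_hu[p]
      }
    }

    # CT attenuation is integer-valued on disk (16-bit stored pixels);
    # round before truth enumeration so file round-trips are lossless
    hu <- round(hu)

    # ---- ground truth by enumeration of the painted masks ----
    roi <- .disk_mask(nr, nc, heart_center, heart_radius + 2)
    truth <- list(
      calcified_pixel_count = sum(roi & hu > 130),
      true_laa_fraction = sum(lab == .lab[["laa"]]) /
        sum(lab %in% c(.lab[["lung"]], .lab[["laa"]])),
      true_muscle_area_cm2 = length(musc_idx) *
        prod(config$pixel_spacing) / 100,
      true_muscle_mean_hu = mean(hu[musc_idx]),
      true_fat_mean_hu = mean(hu[fat_idx]),
      n_muscle_pixels = length(musc_idx),
      n_fat_pixels = length(fat_idx),
      n_lung_pixels = sum(lab %in% c(.lab[["lung"]], .lab[["laa"]])),
      n_laa_pixels = sum(lab == .lab[["laa"]]),
      heart_center = heart_center,
      heart_radius = heart_radius + 2,
      mediastinum_seed = c(round(0.50 * nr), round(0.50 * nc)))
    class(truth) <- "phantom_truth"

    hu <- hu + config$background_offset
    hu <- pmin(pmax(hu, -1024), 3071)
    vox <- array(hu, dim = c(nr, nc, config$n_slices))
    labs <- array(lab, dim = c(nr, nc, config$n_slices))
    attr(labs, "legend") <- .lab
    list(volume = ct_volume(vox, config$pixel_spacing,
                            config$slice_thickness),
         truth = truth, labels = labs)
  })
}

#' Write phantom ground truth as a JSON sidecar
#'
#' @param truth a `phantom_truth` object from [make_phantom()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "phantom_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
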