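#' Write a CT volume to disk
#'
#' Two on-disk representations are supported: a DICOM series (one explicit
#' VR little-endian file per slice, stored 16-bit with rescale slope 1 and
#' intercept -1024) and the MetaImage format (`.mhd` plain-text header plus
#' `.raw` 16-bit payload), a common single-file research container.  DICOM
#' is the reference path; MetaImage exists for fast single-file fixtures.
#'
#' @param volume a [ct_volume].
#' @param path output directory (DICOM) or `.mhd` file path (MetaImage).
#' @param format `"dicom"`, `"mhd"`, or `"auto"` (inferred from `path`:
#'   `.mhd` suffix selects MetaImage, otherwise DICOM).
#' @return `path`, invisibly.
#' @seealso [read_ct()]
#' @export
write_ct <- function(volume, path, format = c("auto", "dicom", "mhd")) {
  stopifnot(inherits(volume, "ct_volume"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mhd$", path, ignore.case = TRUE)) "mhd" else "dicom"
  d <- dim(volume$voxels)
  if (format == "dicom") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    series_uid <- .dcm_uid(paste0("s", paste(d, collapse = ".")))
    locs <- volume$slice_locations %||%
      (seq_len(d[3]) - 1) * volume$slice_thickness
    for (k in seq_len(d[3])) {
      .dcm_write_slice(volume$voxels[, , k],
                       file.path(path, sprintf("slice_%04d.dcm", k)),
                       series_uid = series_uid, instance = k,
                       pixel_spacing = volume$pixel_spacing,
                       slice_thickness = volume$slice_thickness,
                       slice_location = locs[k])
    }
  } else {
    raw_path <- sub("\\.mhd$", ".raw", path, ignore.case = TRUE)
    hdr <- c(
      "ObjectType = Image",
      "NDims = 3",
      sprintf("DimSize = %d %d %d", d[2], d[1], d[3]),
      sprintf("ElementSpacing = %.10g %.10g %.10g",
              volume$pixel_spacing[2], volume$pixel_spacing[1],
              volume$slice_thickness),
      "ElementType = MET_SHORT",
      "ElementByteOrderMSB = False",
      sprintf("ElementDataFile = %s", basename(raw_path)))
    writeLines(hdr, path)
    con <- file(raw_path, "wb")
    on.exit(close(con))
    # MetaImage raster order: x (= column) fastest, then row, then slice
    vals <- as.integer(round(aperm(volume$voxels, c(2, 1, 3))))
    writeBin(vals, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a CT volume
#'
#' Reads either a DICOM series directory or a MetaImage (`.mhd`) file into
#' a [ct_volume] in Hounsfield units.  For DICOM the rescale slope and
#' intercept are applied per slice and spacing is taken from the
#' `PixelSpacing`, `SliceThickness` and `SliceLocation` attributes; a
#' missing `PixelSpacing` is a hard error, as is a directory mixing more
#' than one `SeriesInstanceUID`.
#'
#' @param path DICOM series directory or `.mhd` file.
#' @param format `"dicom"`, `"mhd"`, or `"auto"`.
#' @return A [ct_volume] in HU.
#' @examples
#' vol <- ct_volume(matrix(c(-1000, 0, 40, 400), 8, 8), c(0.7, 0.7))
#' dir <- file.path(tempdir(), "series")
#' write_ct(vol, dir, format = "dicom")
#' back <- read_ct(dir)
#' all.equal(back$voxels, vol$voxels)
#' @export
read_ct <- function(path, format = c("auto", "dicom", "mhd")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mhd$", path, ignore.case = TRUE)) "mhd" else "dicom"
  if (format == "dicom") {
    if (!dir.exists(path)) stop2("DICOM series directory not found: ", path)
    files <- sort(list.files(path, pattern = "\\.dcm$", full.names = TRUE))
    if (length(files) == 0)
      files <- sort(list.files(path, full.names = TRUE))
    if (length(files) == 0) stop2("no files in DICOM directory: ", path)
    slices <- lapply(files, .dcm_read_slice)
    uids <- unique(vapply(slices, `[[`, "", "series_uid"))
    if (length(uids) > 1)
      stop2("directory mixes ", length(uids),
            " DICOM series (SeriesInstanceUID values: ",
            paste(uids, collapse = ", "), ")")
    locs <- vapply(slices, `[[`, 0, "slice_location")
    ord <- if (all(is.finite(locs))) order(locs)
           else order(vapply(slices, `[[`, 0L, "instance"))
    slices <- slices[ord]
    dims <- vapply(slices, function(s) dim(s$hu), integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop2("DICOM slices disagree on matrix size")
    vox <- array(unlist(lapply(slices, `[[`, "hu")),
                 dim = c(dims[1, 1], dims[2, 1], length(slices)))
    ct_volume(vox,
              pixel_spacing = slices[[1]]$pixel_spacing,
              slice_thickness = slices[[1]]$slice_thickness,
              slice_locations = if (all(is.finite(locs))) sort(locs))
  } else {
    if (!file.exists(path)) stop2("MetaImage header not found: ", path)
    lines <- readLines(path)
    kv <- strsplit(lines, "\\s*=\\s*")
    hdr <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
    need <- function(key) {
      if (is.na(hdr[key])) stop2("MetaImage header missing attribute ", key)
      hdr[[key]]
    }
    dimsize <- as.integer(strsplit(need("DimSize"), "\\s+")[[1]])
    spacing <- as.numeric(strsplit(need("ElementSpacing"), "\\s+")[[1]])
    if (need("ElementType") != "MET_SHORT")
      stop2("only MET_SHORT MetaImage volumes are supported")
    raw_path <- file.path(dirname(path), need("ElementDataFile"))
    vals <- readBin(raw_path, "integer", n = prod(dimsize), size = 2,
                    endian = "little")
    vox <- aperm(array(as.numeric(vals),
                       dim = c(dimsize[1], dimsize[2], dimsize[3])),
                 c(2, 1, 3))
    ct_volume(vox, pixel_spacing = c(spacing[2], spacing[1]),
              slice_thickness = spacing[3])
  }
}

#' Default roster column mapping
#'
#' Maps the package's internal field names to the column headers of the
#' screening-trial master sheet (e.g. `"can scr"` for the screen-detected
#' flag, `"finaldeathLC"` for the outcome code, `"pkyr"` for pack-years).
#' Pass a modified copy to [read_roster()] for rosters with other headers.
#'
#' @return Named character vector: internal name -> CSV column header.
#' @export
nlst_column_map <- function() {
  c(pid = "pid", age = "age", gender = "gender", height = "height",
    weight = "weight", pkyr = "pkyr", stage = "stage",
    screen_detected = "can scr", death_lc = "finaldeathLC",
    candx_days = "candx_days", fup_days = "fup_days",
    copd = "copd", histology = "histology")
}

.roster_numeric <- c("age", "height", "weight", "pkyr", "candx_days",
                     "fup_days")

#' Read a subject roster CSV
#'
#' Reads a master-sheet-style CSV into a subject roster data frame with
#' one row per subject.  Column headers are translated through `col_map`
#' (defaulting to the trial's names, see [nlst_column_map()]); when a
#' mapped header is absent but the internal name itself is present, the
#' internal name is used.  Unparseable numeric fields become `NA` with a
#' warning that counts them; a missing `pid` column or duplicated pids are
#' hard errors.
#'
#' @param path CSV file with a header row.
#' @param col_map named character vector as returned by
#'   [nlst_column_map()].
#' @return A `data.frame` of class `subject_roster`.
#' @export
read_roster <- function(path, col_map = nlst_column_map()) {
  if (!file.exists(path)) stop2("roster file not found: ", path)
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                  colClasses = "character")
  out <- list()
  for (field in names(col_map)) {
    col <- col_map[[field]]
    if (col %in% names(raw)) out[[field]] <- raw[[col]]
    else if (field %in% names(raw)) out[[field]] <- raw[[field]]
    else out[[field]] <- rep(NA, nrow(raw))
  }
  if (all(is.na(out$pid)))
    stop2("roster has no pid column (looked for '", col_map[["pid"]], "')")
  if (anyDuplicated(out$pid))
    stop2("duplicate pid values in roster: ",
          paste(unique(out$pid[duplicated(out$pid)]), collapse = ", "))
  n_bad <- 0L
  for (field in .roster_numeric) {
    parsed <- suppressWarnings(as.numeric(out[[field]]))
    n_bad <- n_bad + sum(is.na(parsed) & !is.na(out[[field]]))
    out[[field]] <- parsed
  }
  if (n_bad > 0)
    warn2(n_bad, " numeric roster field(s) were unparseable and set to NA")
  out$screen_detected <- .parse_flag(out$screen_detected)
  out$copd <- .parse_flag(out$copd)
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  class(df) <- c("subject_roster", "data.frame")
  df
}

.parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(trimws(as.character(x)))
  ifelse(x %in% c("1", "true", "yes", "y"), TRUE,
         ifelse(x %in% c("0", "false", "no", "n"), FALSE, NA))
}

#' Write a tabular result to CSV
#'
#' Writes any of the package's tabular objects (subject rosters, matched
#' cohorts, model results, plain data frames) as CSV with a deterministic
#' column order; re-reading reproduces the stored values at full printed
#' precision (15 significant digits).
#'
#' @param x a data frame, `matched_cohort`, or `model_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  if (inherits(x, "matched_cohort")) x <- x$pairs
  if (inherits(x, "model_result")) x <- as.data.frame(x)
  if (!is.data.frame(x)) x <- as.data.frame(x)
  df <- x[, sort(names(x)) , drop = FALSE]
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v)
    ifelse(is.na(v), NA, format(v, digits = 15, trim = TRUE,
                                scientific = FALSE)))
  tryCatch(
    suppressWarnings(
      write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")),
    error = function(e) stop2("cannot write table to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}
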