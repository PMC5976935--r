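# Minimal DICOM support: explicit VR little endian, single-frame CT images.
# Enough for the fixture writer / reader pair used throughout the package;
# not a general DICOM implementation (no sequences, no compressed transfer
# syntaxes).  Stored pixels are 16-bit with rescale slope/intercept, the
# standard CT encoding.

.dcm_long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.dcm_pad <- function(raw_val, pad = as.raw(0L)) {
  if (length(raw_val) %% 2L == 1L) c(raw_val, pad) else raw_val
}

.dcm_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                    endian = "little")

# Encode one data element (explicit VR little endian).
.dcm_element <- function(group, element, vr, value) {
  if (vr %in% c("UI")) {
    val <- .dcm_pad(charToRaw(value), as.raw(0L))
  } else if (vr %in% c("CS", "DS", "IS", "LO", "SH")) {
    val <- .dcm_pad(charToRaw(value), charToRaw(" "))
  } else if (vr == "US") {
    val <- .dcm_uint16(value)
  } else if (vr == "UL") {
    val <- writeBin(as.integer(value), raw(), size = 4, endian = "little")
  } else if (vr == "OW") {
    val <- value  # already raw
  } else stop2("unsupported VR in writer: ", vr)
  hdr <- c(.dcm_uint16(group), .dcm_uint16(element), charToRaw(vr))
  if (vr %in% .dcm_long_vrs) {
    c(hdr, as.raw(c(0L, 0L)),
      writeBin(length(val), raw(), size = 4, endian = "little"), val)
  } else {
    c(hdr, .dcm_uint16(length(val)), val)
  }
}

.dcm_uid <- function(suffix) paste0("1.2.826.0.1.3680043.9.7433.", suffix)

# Write one slice as a DICOM file.  Stored value = HU - intercept with
# slope 1, so stored = HU + 1024 fits unsigned 16 bits.
.dcm_write_slice <- function(slice_hu, path, series_uid, instance,
                             pixel_spacing, slice_thickness,
                             slice_location,
                             slope = 1, intercept = -1024) {
  nr <- nrow(slice_hu); nc <- ncol(slice_hu)
  stored <- round((slice_hu - intercept) / slope)
  if (any(stored < 0 | stored > 65535))
    stop2("stored pixel values out of unsigned 16-bit range")
  # column-fastest (row-major) raster order, the DICOM convention
  pix <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")
  sop_uid <- .dcm_uid(paste0(instance, ".", nr, ".", nc))
  ds <- function(x) format(x, trim = TRUE, scientific = FALSE, digits = 10)

  meta_body <- c(
    .dcm_element(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    .dcm_element(0x0002, 0x0003, "UI", sop_uid),
    .dcm_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"))
  meta <- c(.dcm_element(0x0002, 0x0000, "UL", length(meta_body)), meta_body)

  body <- c(
    .dcm_element(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    .dcm_element(0x0008, 0x0018, "UI", sop_uid),
    .dcm_element(0x0008, 0x0060, "CS", "CT"),
    .dcm_element(0x0018, 0x0050, "DS", ds(slice_thickness)),
    .dcm_element(0x0020, 0x000E, "UI", series_uid),
    .dcm_element(0x0020, 0x0013, "IS", as.character(instance)),
    .dcm_element(0x0020, 0x1041, "DS", ds(slice_location)),
    .dcm_element(0x0028, 0x0002, "US", 1L),
    .dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .dcm_element(0x0028, 0x0010, "US", nr),
    .dcm_element(0x0028, 0x0011, "US", nc),
    .dcm_element(0x0028, 0x0030, "DS",
                 paste0(ds(pixel_spacing[1]), "\\", ds(pixel_spacing[2]))),
    .dcm_element(0x0028, 0x0100, "US", 16L),
    .dcm_element(0x0028, 0x0101, "US", 16L),
    .dcm_element(0x0028, 0x0102, "US", 15L),
    .dcm_element(0x0028, 0x0103, "US", 0L),
    .dcm_element(0x0028, 0x1052, "DS", ds(intercept)),
    .dcm_element(0x0028, 0x1053, "DS", ds(slope)),
    .dcm_element(0x7FE0, 0x0010, "OW", pix))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

# Parse one DICOM file; returns the attributes the package needs.
.dcm_read_slice <- function(path) {
  bytes <- readBin(path, raw(), n = file.info(path)$size)
  if (length(bytes) < 140 ||
      rawToChar(bytes[129:132]) != "DICM")
    stop2("not a DICOM file (missing DICM marker): ", path)
  pos <- 133L
  n <- length(bytes)
  u16 <- function(at) {
    readBin(bytes[at:(at + 1L)], "integer", size = 2, signed = FALSE,
            endian = "little")
  }
  u32 <- function(at) {
    readBin(bytes[at:(at + 3L)], "integer", size = 4, endian = "little")
  }
  out <- list()
  while (pos + 7L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% .dcm_long_vrs) {
      len <- u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L); vstart <- pos + 8L
    }
    vend <- vstart + len - 1L
    if (len > 0 && vend > n) stop2("truncated DICOM element in ", path)
    key <- sprintf("%04X%04X", group, element)
    if (key == "7FE00010") {
      out[[key]] <- bytes[vstart:vend]
    } else if (key %in% c("0020000E", "00200013", "00201041", "00280010",
                          "00280011", "00280030", "00280103", "00281052",
                          "00281053", "00180050")) {
      out[[key]] <- if (vr == "US") u16(vstart)
                    else trimws(rawToChar(bytes[vstart:vend]))
    }
    pos <- vstart + len
  }
  need <- function(key, name) {
    if (is.null(out[[key]]))
      stop2("DICOM file ", basename(path),
            " is missing required attribute ", name)
    out[[key]]
  }
  rows <- need("00280010", "Rows")
  cols <- need("00280011", "Columns")
  spacing <- as.numeric(strsplit(need("00280030", "PixelSpacing"),
                                 "\\\\")[[1]])
  if (length(spacing) != 2L || any(!is.finite(spacing)))
    stop2("DICOM file ", basename(path), " has malformed PixelSpacing")
  slope <- as.numeric(out[["00281053"]] %||% "1")
  intercept <- as.numeric(out[["00281052"]] %||% "0")
  signed <- identical(out[["00280103"]], 1L)
  pix_raw <- need("7FE00010", "PixelData")
  stored <- readBin(pix_raw, "integer", size = 2, signed = signed,
                    endian = "little", n = length(pix_raw) / 2)
  if (length(stored) != rows * cols)
    stop2("DICOM pixel data size mismatch in ", basename(path))
  hu <- matrix(stored * slope + intercept, nrow = rows, ncol = cols,
               byrow = TRUE)
  list(hu = hu,
       series_uid = need("0020000E", "SeriesInstanceUID"),
       instance = as.integer(out[["00200013"]] %||% NA_integer_),
       slice_location = as.numeric(out[["00201041"]] %||% NA_real_),
       slice_thickness = as.numeric(out[["00180050"]] %||% "1"),
       pixel_spacing = spacing)
}
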