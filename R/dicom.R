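# Minimal single-frame DICOM reader/writer.
#
# Scope: uncompressed little-endian transfer syntaxes only (explicit VR
# 1.2.840.10008.1.2.1 and implicit VR 1.2.840.10008.1.2), single-frame
# grayscale pixel data, 8 or 16 bits allocated. This covers the slices the
# pipeline consumes; sequences, big-endian and compressed syntaxes are
# rejected with a clear error.

.DICOM_EXPLICIT <- "1.2.840.10008.1.2.1"
.DICOM_IMPLICIT <- "1.2.840.10008.1.2"
.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.u16_to_raw <- function(x) {
  x <- as.integer(round(x))
  x[x > 32767L] <- x[x > 32767L] - 65536L
  writeBin(x, raw(), size = 2L, endian = "little")
}

.u32_to_raw <- function(x) {
  writeBin(as.integer(x), raw(), size = 4L, endian = "little")
}

.str_to_raw <- function(s) {
  r <- charToRaw(s)
  if (length(r) %% 2L == 1L) r <- c(r, as.raw(0L))  # even length padding
  r
}

.dicom_element <- function(group, elem, vr, value_raw) {
  head <- c(.u16_to_raw(group), .u16_to_raw(elem), charToRaw(vr))
  if (vr %in% .LONG_VRS) {
    c(head, as.raw(c(0L, 0L)), .u32_to_raw(length(value_raw)), value_raw)
  } else {
    c(head, .u16_to_raw(length(value_raw)), value_raw)
  }
}

#' Write a slice as a minimal single-frame DICOM file
#'
#' Pixels must be integer-valued; they are stored as unsigned 16-bit with a
#' RescaleIntercept equal to the image minimum (RescaleSlope 1), so the HU
#' values recovered on read equal the input exactly, including negatives.
#'
#' @param image A [ct_image] with integer-valued pixels.
#' @param path Output path.
#' @param instance_number Optional integer InstanceNumber (slice ordering).
#' @return `path`, invisibly.
#' @export
write_dicom_slice <- function(image, path, instance_number = NULL) {
  px <- image$pixels
  if (max(abs(px - round(px))) > 1e-9) {
    stopf("DICOM writer requires integer-valued pixels")
  }
  px <- round(px)
  intercept <- min(px)
  stored <- px - intercept
  if (max(stored) > 65535) stopf("pixel dynamic range exceeds 16 bits")

  meta <- c(
    .dicom_element(0x0002, 0x0010, "UI", .str_to_raw(.DICOM_EXPLICIT))
  )
  meta <- c(.dicom_element(0x0002, 0x0000, "UL", .u32_to_raw(length(meta))),
            meta)

  ds <- raw(0)
  if (!is.null(instance_number)) {
    ds <- c(ds, .dicom_element(0x0020, 0x0013, "IS",
                               .str_to_raw(as.character(instance_number))))
  }
  spacing <- sprintf("%g\\%g", image$spacing_mm[1], image$spacing_mm[2])
  ds <- c(
    ds,
    .dicom_element(0x0028, 0x0002, "US", .u16_to_raw(1L)),
    .dicom_element(0x0028, 0x0010, "US", .u16_to_raw(nrow(px))),
    .dicom_element(0x0028, 0x0011, "US", .u16_to_raw(ncol(px))),
    .dicom_element(0x0028, 0x0030, "DS", .str_to_raw(spacing)),
    .dicom_element(0x0028, 0x0100, "US", .u16_to_raw(16L)),
    .dicom_element(0x0028, 0x0101, "US", .u16_to_raw(16L)),
    .dicom_element(0x0028, 0x0102, "US", .u16_to_raw(15L)),
    .dicom_element(0x0028, 0x0103, "US", .u16_to_raw(0L)),
    .dicom_element(0x0028, 0x1052, "DS",
                   .str_to_raw(as.character(intercept))),
    .dicom_element(0x0028, 0x1053, "DS", .str_to_raw("1")),
    # DICOM pixel order is row-major (top row first).
    .dicom_element(0x7FE0, 0x0010, "OW", .u16_to_raw(as.vector(t(stored))))
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), meta, ds), con)
  invisible(path)
}

.parse_element <- function(bytes, pos, explicit) {
  grp <- readBin(bytes[pos:(pos + 1L)], "integer", size = 2L, signed = FALSE,
                 endian = "little")
  ele <- readBin(bytes[(pos + 2L):(pos + 3L)], "integer", size = 2L,
                 signed = FALSE, endian = "little")
  pos <- pos + 4L
  vr <- NA_character_
  if (explicit) {
    vr <- rawToChar(bytes[pos:(pos + 1L)])
    pos <- pos + 2L
    if (vr %in% .LONG_VRS) {
      pos <- pos + 2L  # reserved
      len <- readBin(bytes[pos:(pos + 3L)], "integer", size = 4L,
                     endian = "little")
      pos <- pos + 4L
    } else {
      len <- readBin(bytes[pos:(pos + 1L)], "integer", size = 2L,
                     signed = FALSE, endian = "little")
      pos <- pos + 2L
    }
  } else {
    len <- readBin(bytes[pos:(pos + 3L)], "integer", size = 4L,
                   endian = "little")
    pos <- pos + 4L
  }
  if (len == -1L) stopf("DICOM undefined-length elements are unsupported")
  value <- if (len > 0L) bytes[pos:(pos + len - 1L)] else raw(0)
  list(group = grp, elem = ele, vr = vr, value = value, pos = pos + len)
}

.raw_us <- function(v) {
  readBin(v, "integer", n = length(v) %/% 2L, size = 2L, signed = FALSE,
          endian = "little")
}

.raw_str <- function(v) trimws(rawToChar(v[v != as.raw(0L)]))

#' Read a minimal single-frame DICOM slice
#'
#' Applies RescaleSlope/RescaleIntercept so pixel values are in HU. The
#' InstanceNumber, when present, is attached as an attribute and used by
#' [read_scan()] for slice ordering. Missing PixelSpacing triggers a warning
#' and the 0.5 mm x 0.5 mm default.
#'
#' @param path File path.
#' @return A [ct_image].
#' @export
read_dicom_slice <- function(path) {
  n <- file.size(path)
  if (is.na(n) || n < 140) stopf("unreadable DICOM '%s': file too small", path)
  bytes <- readBin(path, "raw", n)
  if (rawToChar(bytes[129:132]) != "DICM") {
    stopf("unreadable DICOM '%s': missing DICM magic", path)
  }
  pos <- 133L
  tags <- new.env(parent = emptyenv())
  ts <- .DICOM_EXPLICIT
  # File meta group (0002,xxxx) is always explicit VR little endian.
  while (pos + 7L <= n) {
    el <- .parse_element(bytes, pos, explicit = TRUE)
    if (el$group != 0x0002) break
    if (el$elem == 0x0010) ts <- .raw_str(el$value)
    pos <- el$pos
  }
  explicit <- switch(ts,
                     "1.2.840.10008.1.2.1" = TRUE,
                     "1.2.840.10008.1.2" = FALSE,
                     stopf("unsupported DICOM transfer syntax '%s'", ts))
  while (pos + 7L <= n) {
    el <- .parse_element(bytes, pos, explicit = explicit)
    key <- sprintf("%04x%04x", el$group, el$elem)
    assign(key, el, envir = tags)
    pos <- el$pos
  }
  getv <- function(key) if (exists(key, envir = tags)) get(key, envir = tags)
    else NULL

  rows_el <- getv("00280010"); cols_el <- getv("00280011")
  pix_el <- getv("7fe00010")
  if (is.null(rows_el) || is.null(cols_el) || is.null(pix_el)) {
    stopf("unreadable DICOM '%s': missing Rows/Columns/PixelData", path)
  }
  rows <- .raw_us(rows_el$value)[1]
  cols <- .raw_us(cols_el$value)[1]
  bits <- if (!is.null(getv("00280100"))) .raw_us(getv("00280100")$value)[1]
    else 16L
  pixrep <- if (!is.null(getv("00280103"))) .raw_us(getv("00280103")$value)[1]
    else 0L
  slope <- if (!is.null(getv("00281053")))
    as.numeric(.raw_str(getv("00281053")$value)) else 1
  intercept <- if (!is.null(getv("00281052")))
    as.numeric(.raw_str(getv("00281052")$value)) else 0

  vals <- if (bits == 16L) {
    readBin(pix_el$value, "integer", n = rows * cols, size = 2L,
            signed = (pixrep == 1L), endian = "little")
  } else if (bits == 8L) {
    readBin(pix_el$value, "integer", n = rows * cols, size = 1L,
            signed = FALSE)
  } else {
    stopf("unsupported BitsAllocated %d in '%s'", bits, path)
  }
  if (length(vals) < rows * cols) {
    stopf("unreadable DICOM '%s': truncated pixel data", path)
  }
  px <- matrix(vals * slope + intercept, nrow = rows, ncol = cols,
               byrow = TRUE)

  sp_el <- getv("00280030")
  if (is.null(sp_el)) {
    warnf("DICOM '%s' has no PixelSpacing; assuming 0.5 mm x 0.5 mm", path)
    spacing <- c(0.5, 0.5)
  } else {
    spacing <- as.numeric(strsplit(.raw_str(sp_el$value), "\\\\")[[1]])[1:2]
  }
  img <- ct_image(px, spacing_mm = spacing, source_id = path)
  inst_el <- getv("00200013")
  attr(img, "instance_number") <- if (is.null(inst_el)) NA_integer_
    else as.integer(.raw_str(inst_el$value))
  img
}
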