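# Canonical in-memory image types and slice/scan readers.
#
# Coordinate convention (shared by every module): (row, col), 1-based,
# row 1 at the top of the image.

#' Construct a CT slice object
#'
#' A `ct_image` holds one 2-D grayscale slice (Hounsfield units or any
#' monotone intensity scale) together with its pixel spacing. It is the unit
#' every pipeline stage consumes; downstream quantization makes the texture
#' descriptor invariant to the absolute intensity scale per sub-band.
#'
#' @param pixels Numeric matrix of intensities; must be non-empty with all
#'   values finite.
#' @param spacing_mm Length-2 numeric `(row, col)` pixel size in millimetres;
#'   both components must be positive. A scalar is recycled.
#' @param source_id Opaque identifier string (e.g. the file the slice came
#'   from).
#' @return An object of class `ct_image` with fields `pixels`, `spacing_mm`,
#'   `source_id`.
#' @examples
#' img <- ct_image(matrix(0, 4, 4))
#' dim(img$pixels)
#' @export
ct_image <- function(pixels, spacing_mm = c(0.5, 0.5), source_id = "") {
  if (!is.matrix(pixels) || length(pixels) == 0L) {
    stopf("`pixels` must be a non-empty matrix")
  }
  storage.mode(pixels) <- "double"
  if (!all(is.finite(pixels))) stopf("`pixels` must be all finite")
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 2L)
  spacing_mm <- as.double(spacing_mm)
  if (length(spacing_mm) != 2L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    stopf("`spacing_mm` must be two positive finite numbers")
  }
  structure(
    list(pixels = pixels, spacing_mm = spacing_mm,
         source_id = as.character(source_id)),
    class = "ct_image"
  )
}

#' @export
print.ct_image <- function(x, ...) {
  cat(sprintf("<ct_image> %d x %d px, %.3g x %.3g mm/px, range [%g, %g]%s\n",
              nrow(x$pixels), ncol(x$pixels),
              x$spacing_mm[1], x$spacing_mm[2],
              min(x$pixels), max(x$pixels),
              if (nzchar(x$source_id)) paste0(", src=", x$source_id) else ""))
  invisible(x)
}

# Coerce a bare matrix into a ct_image; pass ct_image through.
as_ct_image <- function(x, spacing_mm = c(0.5, 0.5)) {
  if (inherits(x, "ct_image")) return(x)
  ct_image(as.matrix(x), spacing_mm = spacing_mm)
}

#' Construct a CT scan object
#'
#' An ordered collection of slices from one scan, optionally with per-slice
#' binary ground-truth labels (1 = slice contains a nodule).
#'
#' @param slices List of [ct_image] objects (at least one).
#' @param labels Optional integer/logical vector, one entry per slice.
#' @param scan_id Identifier string.
#' @return An object of class `ct_scan`.
#' @export
ct_scan <- function(slices, labels = NULL, scan_id = "") {
  if (!is.list(slices) || length(slices) == 0L) {
    stopf("`slices` must be a non-empty list of ct_image objects")
  }
  if (!all(vapply(slices, inherits, logical(1), "ct_image"))) {
    stopf("every slice must be a ct_image")
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != length(slices)) {
      stopf("`labels` must have one entry per slice (%d != %d)",
            length(labels), length(slices))
    }
    if (!all(labels %in% c(0L, 1L))) stopf("`labels` must be binary 0/1")
  }
  structure(list(scan_id = as.character(scan_id), slices = slices,
                 labels = labels),
            class = "ct_scan")
}

#' @export
print.ct_scan <- function(x, ...) {
  cat(sprintf("<ct_scan> '%s': %d slice(s)%s\n", x$scan_id, length(x$slices),
              if (is.null(x$labels)) "" else
                sprintf(", %d labelled positive", sum(x$labels))))
  invisible(x)
}

.format_from_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = "png",
         tif = , tiff = "tiff",
         dcm = , dicom = "dicom",
         stopf("cannot infer image format from '%s'; pass `format`", path))
}

#' Read one CT slice from disk
#'
#' Supports single-frame DICOM (values rescaled to HU via RescaleSlope and
#' RescaleIntercept), and 8/16-bit grayscale PNG and TIFF. Integer pixel
#' values are preserved exactly for PNG/TIFF. Color images are rejected: the
#' pipeline is defined on grayscale CT data.
#'
#' @param path File path.
#' @param format One of `"auto"`, `"png"`, `"tiff"`, `"dicom"`; `"auto"`
#'   infers from the file extension.
#' @param spacing_mm Pixel spacing to attach for formats without spacing
#'   metadata (PNG/TIFF). For DICOM the PixelSpacing element is used; when
#'   absent a warning is issued and 0.5 mm (the database default) is assumed.
#' @return A [ct_image].
#' @export
read_slice <- function(path, format = c("auto", "png", "tiff", "dicom"),
                       spacing_mm = c(0.5, 0.5)) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file does not exist: '%s'", path)
  if (format == "auto") format <- .format_from_path(path)
  switch(format,
         png = .read_png_slice(path, spacing_mm),
         tiff = .read_tiff_slice(path, spacing_mm),
         dicom = read_dicom_slice(path))
}

.read_png_slice <- function(path, spacing_mm) {
  p <- tryCatch(png::readPNG(path),
                error = function(e) stopf("unreadable PNG '%s': %s", path,
                                          conditionMessage(e)))
  if (length(dim(p)) == 3L) {
    if (dim(p)[3] == 2L) p <- p[, , 1L]  # gray + alpha
    else stopf("color PNG rejected ('%s'); pipeline is grayscale-only", path)
  }
  # readPNG returns value / (2^depth - 1); recover the stored integers.
  v8 <- p * 255
  pixels <- if (max(abs(v8 - round(v8))) < 1e-9) round(v8) else round(p * 65535)
  ct_image(pixels, spacing_mm = spacing_mm, source_id = path)
}

.read_tiff_slice <- function(path, spacing_mm) {
  p <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                error = function(e) stopf("unreadable TIFF '%s': %s", path,
                                          conditionMessage(e)))
  if (length(dim(p)) == 3L) {
    if (dim(p)[3] == 2L) p <- p[, , 1L]
    else stopf("color TIFF rejected ('%s'); pipeline is grayscale-only", path)
  }
  ct_image(p, spacing_mm = spacing_mm, source_id = path)
}

#' Write one CT slice to disk
#'
#' PNG/TIFF require non-negative integer-valued pixels within the bit depth;
#' the write/read round trip is then lossless. DICOM stores pixels as
#' unsigned 16-bit with a rescale intercept, so arbitrary integer-valued
#' images (including negative HU) round-trip exactly.
#'
#' @param image A [ct_image].
#' @param path Output path.
#' @param format `"png"`, `"tiff"` or `"dicom"` (default inferred from
#'   extension).
#' @param bitdepth 8 for PNG; 8 or 16 for TIFF. PNG output is 8-bit (16-bit
#'   grayscale is carried by TIFF or DICOM).
#' @param instance_number Optional DICOM InstanceNumber.
#' @return `path`, invisibly.
#' @export
write_slice <- function(image, path, format = c("auto", "png", "tiff", "dicom"),
                        bitdepth = NULL, instance_number = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- .format_from_path(path)
  px <- image$pixels
  if (format %in% c("png", "tiff")) {
    if (is.null(bitdepth)) bitdepth <- if (format == "png") 8L else 16L
    if (format == "png" && bitdepth != 8L) {
      stopf("PNG output is 8-bit; use TIFF or DICOM for 16-bit data")
    }
    maxv <- 2^bitdepth - 1
    if (max(abs(px - round(px))) > 1e-9 || min(px) < 0 || max(px) > maxv) {
      stopf("pixels must be integers in [0, %d] for %s output; rescale first",
            maxv, format)
    }
    scaled <- round(px) / maxv
    if (format == "png") {
      png::writePNG(scaled, target = path)
    } else {
      tiff::writeTIFF(scaled, where = path, bits.per.sample = bitdepth)
    }
  } else {
    write_dicom_slice(image, path, instance_number = instance_number)
  }
  invisible(path)
}

#' Read a directory of slices as one CT scan
#'
#' Slices are ordered by DICOM InstanceNumber when every file provides one,
#' otherwise by lexicographic filename order. Per-slice binary labels are
#' loaded from an optional sidecar `labels.csv` (columns `filename,label`);
#' files absent from the sidecar default to label 0.
#'
#' @param dir Directory containing >= 1 readable slice file (png/tif/tiff/dcm).
#' @param scan_id Identifier (defaults to the directory basename).
#' @param spacing_mm Spacing for formats without spacing metadata.
#' @return A [ct_scan].
#' @export
read_scan <- function(dir, scan_id = basename(dir), spacing_mm = c(0.5, 0.5)) {
  if (!dir.exists(dir)) stopf("directory does not exist: '%s'", dir)
  files <- sort(list.files(dir, pattern = "\\.(png|tif|tiff|dcm|dicom)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) stopf("no readable slice files in '%s'", dir)
  slices <- lapply(files, function(f) {
    tryCatch(read_slice(f, spacing_mm = spacing_mm),
             error = function(e) stopf("failed to read slice '%s': %s",
                                       basename(f), conditionMessage(e)))
  })
  dims <- vapply(slices, function(s) dim(s$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stopf("mixed slice shapes in '%s'", dir)
  }
  inst <- vapply(slices, function(s) {
    v <- attr(s, "instance_number")
    if (is.null(v) || is.na(v)) NA_integer_ else as.integer(v)
  }, integer(1))
  ord <- if (all(!is.na(inst))) order(inst, basename(files)) else
    seq_along(files)
  slices <- slices[ord]
  files <- files[ord]

  labels <- NULL
  sidecar <- file.path(dir, "labels.csv")
  if (file.exists(sidecar)) {
    tab <- utils::read.csv(sidecar, stringsAsFactors = FALSE)
    if (!all(c("filename", "label") %in% names(tab))) {
      stopf("sidecar '%s' must have columns filename,label", sidecar)
    }
    labels <- integer(length(files))
    m <- match(basename(files), tab$filename)
    labels[!is.na(m)] <- as.integer(tab$label[m[!is.na(m)]])
  }
  ct_scan(slices, labels = labels, scan_id = scan_id)
}
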