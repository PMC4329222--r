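test_that("ct_image validates its invariants", {
  expect_s3_class(ct_image(matrix(0, 4, 4)), "ct_image")
  expect_error(ct_image(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(ct_image(matrix(c(1, NA), 2, 1)), "finite")
  expect_error(ct_image(matrix(0, 2, 2), spacing_mm = c(0.5, -1)), "positive")
})

test_that("PNG and TIFF round trips are lossless for integer images", {
  set.seed(42)
  img16 <- ct_image(matrix(sample(0:65535, 256, replace = TRUE), 16, 16))
  t16 <- tempfile(fileext = ".tiff")
  write_slice(img16, t16)
  expect_identical(read_slice(t16)$pixels, img16$pixels)

  img8 <- ct_image(matrix(sample(0:255, 256, replace = TRUE), 16, 16))
  p8 <- tempfile(fileext = ".png")
  write_slice(img8, p8)
  expect_identical(read_slice(p8)$pixels, img8$pixels)

  # PNG output is 8-bit only; deeper data goes to TIFF/DICOM
  expect_error(write_slice(img16, tempfile(fileext = ".png")),
               "\\[0, 255\\]")
  expect_error(write_slice(img16, tempfile(fileext = ".png"),
                           bitdepth = 16L), "8-bit")

  zero <- tempfile(fileext = ".png")
  write_slice(ct_image(matrix(0, 4, 4)), zero)
  z <- read_slice(zero)
  expect_true(all(z$pixels == 0))
  expect_identical(dim(z$pixels), c(4L, 4L))
})

test_that("color inputs are rejected, not converted", {
  path <- tempfile(fileext = ".png")
  png::writePNG(array(stats::runif(2 * 2 * 3), dim = c(2, 2, 3)), path)
  expect_error(read_slice(path), "grayscale")
})

test_that("DICOM rescale slope/intercept yields HU values", {
  path <- tempfile(fileext = ".dcm")
  make_test_dicom(path, n = 4L, raw_value = 1024L, slope = 1,
                  intercept = -1024)
  img <- read_slice(path)
  expect_true(all(img$pixels == 0))
  expect_equal(img$spacing_mm, c(0.5, 0.5))
})

test_that("implicit-VR DICOM parses identically", {
  path <- tempfile(fileext = ".dcm")
  make_test_dicom(path, n = 4L, raw_value = 30L, slope = 2, intercept = 5,
                  implicit = TRUE)
  img <- read_slice(path)
  expect_true(all(img$pixels == 65))
})

test_that("DICOM without spacing warns and uses the 0.5 mm default", {
  path <- tempfile(fileext = ".dcm")
  make_test_dicom(path, spacing = NULL)
  expect_warning(img <- read_slice(path), "PixelSpacing")
  expect_equal(img$spacing_mm, c(0.5, 0.5))
})

test_that("DICOM write/read round-trips HU values including negatives", {
  set.seed(7)
  img <- ct_image(matrix(sample(-1024:3071, 64, replace = TRUE), 8, 8),
                  spacing_mm = c(0.7, 0.7))
  path <- tempfile(fileext = ".dcm")
  write_dicom_slice(img, path, instance_number = 12L)
  back <- read_slice(path)
  expect_identical(back$pixels, img$pixels)
  expect_equal(back$spacing_mm, c(0.7, 0.7))
  expect_identical(attr(back, "instance_number"), 12L)
})

test_that("read_scan orders slices and loads the label sidecar", {
  dir <- file.path(tempfile(), "scanA")
  dir.create(dir, recursive = TRUE)
  for (i in 1:3) {
    write_slice(ct_image(matrix(i, 4, 4)), file.path(dir,
                                                     sprintf("%03d.png", i)),
                bitdepth = 8L)
  }
  writeLines(c("filename,label", "002.png,1"),
             file.path(dir, "labels.csv"))
  sc <- read_scan(dir)
  expect_length(sc$slices, 3L)
  expect_equal(sc$labels, c(0L, 1L, 0L))
  expect_equal(vapply(sc$slices, function(s) s$pixels[1, 1], numeric(1)),
               c(1, 2, 3))
})

test_that("read_scan uses DICOM InstanceNumber over filename order", {
  dir <- tempfile()
  dir.create(dir)
  # filenames deliberately misordered relative to instance numbers
  vals <- c(a = 3L, b = 1L, c = 2L)
  for (nm in names(vals)) {
    write_dicom_slice(ct_image(matrix(as.numeric(vals[nm]), 4, 4)),
                      file.path(dir, paste0(nm, ".dcm")),
                      instance_number = vals[nm])
  }
  sc <- read_scan(dir)
  expect_equal(vapply(sc$slices, function(s) s$pixels[1, 1], numeric(1)),
               c(1, 2, 3))
})

test_that("read_scan error paths name the offender", {
  empty <- tempfile(); dir.create(empty)
  expect_error(read_scan(empty), "no readable slice")

  bad <- tempfile(); dir.create(bad)
  writeLines("not a png", file.path(bad, "corrupt.png"))
  expect_error(read_scan(bad), "corrupt.png")

  mixed <- tempfile(); dir.create(mixed)
  write_slice(ct_image(matrix(0, 4, 4)), file.path(mixed, "a.png"),
              bitdepth = 8L)
  write_slice(ct_image(matrix(0, 6, 6)), file.path(mixed, "b.png"),
              bitdepth = 8L)
  expect_error(read_scan(mixed), "mixed")
})
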