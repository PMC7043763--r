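test_that("metadata and channel containers enforce their invariants", {
  m <- image_meta(64, 48, 0.117)
  expect_equal(m$width_px, 64L)
  expect_error(image_meta(0, 10, 0.1), class = "fd_value_error")
  expect_error(image_meta(10, 10, -1), class = "fd_value_error")

  px <- matrix(runif(48 * 64), 48, 64)
  ci <- channel_image(px, m, channel_role = "nuclear")
  expect_s3_class(ci, "fd_channel_image")
  expect_error(channel_image(px[1:10, ], m), class = "fd_dimension_error")
  expect_error(channel_image(px - 2, m), class = "fd_value_error")
  expect_error(channel_image(px * NA, m), class = "fd_value_error")

  expect_error(label_mask(matrix(-1L, 2, 2)), class = "fd_value_error")
  expect_s3_class(label_mask(matrix(c(TRUE, FALSE), 2, 2)), "fd_label_mask")
})

test_that("read_image_pair normalizes PNG pairs and rejects mismatches", {
  dir <- withr::local_tempdir()
  set.seed(1)
  # full-range 8-bit: quantized values k/255, max exactly 255/255 = 1
  vals <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
  vals[1] <- 255L
  png::writePNG(vals / 255, file.path(dir, "nuc.png"))
  png::writePNG(vals / 255, file.path(dir, "foc.png"))
  pr <- read_image_pair(file.path(dir, "nuc.png"), file.path(dir, "foc.png"),
                        pixel_size_um = 0.117)
  expect_identical(pr$nuclear$meta, pr$foci$meta)
  expect_equal(pr$nuclear$meta$pixel_size_um, 0.117)
  expect_equal(max(pr$foci$pixels), 1.0)
  # normalization is monotone: pixel intensity order preserved
  o <- order(vals)
  expect_true(all(diff(pr$foci$pixels[o]) >= 0))

  png::writePNG(matrix(0.5, 32, 32), file.path(dir, "small.png"))
  expect_error(read_image_pair(file.path(dir, "nuc.png"),
                               file.path(dir, "small.png"), 0.117),
               class = "fd_dimension_error")
  expect_error(read_image_pair(file.path(dir, "missing.png"),
                               file.path(dir, "foc.png"), 0.117),
               class = "fd_io_error")
  # genuine RGB is ambiguous
  rgb <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  png::writePNG(rgb, file.path(dir, "rgb.png"))
  expect_error(read_image_pair(file.path(dir, "rgb.png"),
                               file.path(dir, "rgb.png"), 0.117),
               class = "fd_format_error")
})

test_that("TIFF codec round-trips 8/16-bit single- and multi-page images", {
  dir <- withr::local_tempdir()
  set.seed(2)
  m1 <- matrix(sample(0:65535, 40 * 56, replace = TRUE) / 65535, 40, 56)
  m2 <- matrix(sample(0:65535, 40 * 56, replace = TRUE) / 65535, 40, 56)
  p <- file.path(dir, "pair.tif")
  write_gray_image(list(m1, m2), p, bits = 16)
  expect_equal(read_gray_image(p, page = 1), m1, tolerance = 1e-12)
  expect_equal(read_gray_image(p, page = 2), m2, tolerance = 1e-12)

  # two-page TIFF as a registered channel pair
  pr <- read_image_pair(p, p, pixel_size_um = 162.6 / 1388)
  expect_equal(pr$nuclear$pixels, m1, tolerance = 1e-12)
  expect_equal(pr$foci$pixels, m2, tolerance = 1e-12)
  expect_equal(pr$foci$meta$pixel_size_um, 162.6 / 1388)

  p8 <- file.path(dir, "gray8.tif")
  v8 <- matrix(sample(0:255, 30 * 20, replace = TRUE) / 255, 30, 20)
  write_gray_image(v8, p8, bits = 8)
  expect_equal(read_gray_image(p8), v8, tolerance = 1e-12)

  expect_error(read_gray_image(p, page = 3), class = "fd_format_error")
  writeLines("not a tiff", file.path(dir, "junk.tif"))
  expect_error(read_gray_image(file.path(dir, "junk.tif")),
               class = "fd_format_error")
})

test_that("rescale_to_pixel_size follows the printed field geometry", {
  # identity
  img <- channel_image(matrix(runif(32 * 48), 32, 48), pixel_size_um = 0.1172)
  expect_identical(rescale_to_pixel_size(img, 0.1172), img)

  # 40x field resampled to the 63x pixel size: 1388 * 103.2/162.6 -> 881
  wide <- channel_image(matrix(0.5, 16, 1388), pixel_size_um = 103.2 / 1388)
  out <- rescale_to_pixel_size(wide, 162.6 / 1388)
  expect_equal(out$meta$width_px, 881L)
  expect_equal(out$meta$pixel_size_um, 162.6 / 1388)
  # constant image stays constant
  expect_equal(max(abs(out$pixels - 0.5)), 0, tolerance = 1e-9)

  # down then up returns the original dimensions within 1 px per axis
  img2 <- channel_image(matrix(runif(100 * 140), 100, 140), pixel_size_um = 0.1)
  f <- 1.7
  down <- rescale_to_pixel_size(img2, 0.1 * f)
  back <- rescale_to_pixel_size(down, 0.1)
  expect_lte(abs(back$meta$width_px - 140L), 1L)
  expect_lte(abs(back$meta$height_px - 100L), 1L)

  expect_error(rescale_to_pixel_size(img2, -0.1), class = "fd_value_error")
})

test_that("reports and center lists round-trip", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "report.csv")
  rows <- data.frame(model = c("MLP", "RF"), f1 = c(0.914, 0.879),
                     mcc = c(0.7874945, 0.7933))
  write_report(rows, p)
  back <- read_report(p)
  expect_equal(back$f1, rows$f1, tolerance = 1e-9)
  expect_equal(back$mcc, rows$mcc, tolerance = 1e-9)
  expect_equal(nrow(read_report(p)), 2L)
  expect_error(write_report(data.frame(), p), class = "fd_value_error")
  expect_error(write_report(rows, file.path(dir, "no/such/dir/x.csv")),
               class = "fd_io_error")

  cp <- file.path(dir, "centers.json")
  centers <- cbind(row = c(10.5, 20), col = c(3, 7.25))
  write_centers(centers, cp)
  back <- read_centers(cp)
  expect_equal(unname(back), unname(centers))
  # JSON convention: 0-based, x = column
  j <- jsonlite::fromJSON(cp)
  expect_equal(j$x, centers[, 2] - 1)
  expect_equal(j$y, centers[, 1] - 1)
})
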