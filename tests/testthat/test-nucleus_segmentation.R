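test_that("otsu_threshold matches an exhaustive between-class-variance search", {
  # perfect bimodal separation
  x <- matrix(rep(c(0.1, 0.9), each = 50), 10, 10)
  thr <- otsu_threshold(x)
  expect_gt(thr, 0.1)
  expect_lt(thr, 0.9)

  # the stated 6-pixel case
  x6 <- matrix(c(0, 0, 0, 1, 1, 1), 2, 3)
  expect_identical(x6 > otsu_threshold(x6), oracle_otsu_split(x6))

  # property: class split equals brute-force search on random images
  set.seed(11)
  for (rep in 1:8) {
    px <- matrix(sample(0:255, 200, replace = TRUE) / 255, 10, 20)
    expect_identical(px > otsu_threshold(px), oracle_otsu_split(px))
  }

  expect_error(otsu_threshold(matrix(0.4, 5, 5)), class = "fd_degenerate_error")
})

test_that("segment_nuclei finds, sizes and splits planted nuclei", {
  cfg <- small_seg_cfg()
  blank <- channel_image(matrix(0, 64, 64), pixel_size_um = 1,
                         channel_role = "nuclear")
  expect_identical(segment_nuclei(blank, cfg), list())

  # three well-separated disks
  centers <- rbind(c(40, 40), c(40, 130), c(130, 85))
  px <- disk_scene(170, 170, centers, radius = 20)
  img <- channel_image(px, pixel_size_um = 1, channel_role = "nuclear")
  rois <- segment_nuclei(img, cfg)
  expect_length(rois, 3L)
  planted_area <- sum(disk_mask(170, 170, 40, 40, 20))
  for (r in rois) {
    expect_lt(abs(r$area_px - planted_area) / planted_area, 0.10)
    expect_equal(r$area_px, sum(r$mask))
    # bbox tightly bounds the mask (half-open)
    rows <- range(which(rowSums(r$mask) > 0))
    cols <- range(which(colSums(r$mask) > 0))
    expect_equal(unname(r$bbox),
                 c(rows[1], cols[1], rows[2] + 1L, cols[2] + 1L))
  }
  # disjointness
  expect_lte(max(Reduce(`+`, lapply(rois, function(r) r$mask + 0))), 1)

  # two overlapping disks (r = 30, centers 40 px apart): one connected
  # component, split into two by the watershed
  centers2 <- rbind(c(60, 50), c(60, 90))
  px2 <- disk_scene(120, 140, centers2, radius = 30)
  img2 <- channel_image(px2, pixel_size_um = 1, channel_role = "nuclear")
  binary <- px2 > otsu_threshold(px2)
  expect_equal(max(focidetect:::cpp_label(binary, 8L)), 1L)  # merged w/o watershed
  rois2 <- segment_nuclei(img2, cfg)
  expect_length(rois2, 2L)
})

test_that("segmentation is rotation-consistent and count-monotone", {
  cfg <- small_seg_cfg()
  sc <- generate_scene(small_scene_cfg(5))
  rois <- segment_nuclei(sc$nuclear, cfg)
  expect_gt(length(rois), 0)

  rot <- channel_image(sc$nuclear$pixels[nrow(sc$nuclear$pixels):1,
                                         ncol(sc$nuclear$pixels):1],
                       pixel_size_um = 1, channel_role = "nuclear")
  rois_rot <- segment_nuclei(rot, cfg)
  expect_length(rois_rot, length(rois))
  # corresponding rotated masks: compare sorted centroids and areas
  summarize <- function(rs, H, W, flip) {
    t(vapply(rs, function(r) {
      idx <- which(r$mask, arr.ind = TRUE)
      ct <- colMeans(idx)
      if (flip) ct <- c(H + 1 - ct[1], W + 1 - ct[2])
      c(ct, r$area_px)
    }, numeric(3)))
  }
  H <- nrow(rot$pixels); W <- ncol(rot$pixels)
  a <- summarize(rois, H, W, FALSE)
  b <- summarize(rois_rot, H, W, TRUE)
  a <- a[order(a[, 1], a[, 2]), , drop = FALSE]
  b <- b[order(b[, 1], b[, 2]), , drop = FALSE]
  expect_equal(a[, 1:2], b[, 1:2], tolerance = 0.05)
  expect_equal(a[, 3], b[, 3], tolerance = 0.05)

  # adding a well-separated nucleus (on padded canvas) increases the
  # count by exactly 1
  px <- sc$nuclear$pixels
  wide <- cbind(px, matrix(0, nrow(px), 60))
  wide <- pmin(wide + disk_scene(nrow(wide), ncol(wide),
                                 rbind(c(60, ncol(px) + 30)), radius = 16), 1)
  aug <- channel_image(wide, pixel_size_um = 1, channel_role = "nuclear")
  expect_length(segment_nuclei(aug, cfg), length(rois) + 1L)
})
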