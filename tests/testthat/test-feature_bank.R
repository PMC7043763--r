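test_that("bank configurations carry the published channel arithmetic", {
  full <- full_bank_config()
  expect_equal(n_bank_channels(full), 173L)
  expect_equal(full$sizes_px, c(2L, 3L, 4L, 5L, 8L, 10L, 15L, 20L, 25L, 30L, 35L))
  expect_equal(full$gabor_frequencies, c(0.08, 0.10, 0.13, 0.16, 0.2))
  expect_length(full$sized_filters, 15L)
  # sized channels alone: 15 x 11
  expect_equal(length(full$sized_filters) * length(full$sizes_px), 165L)

  red <- reduced_bank_config()
  expect_equal(n_bank_channels(red), 36L)
  expect_equal(red$sizes_px, c(2L, 10L, 30L))
  expect_equal(red$gabor_frequencies, c(0.08, 0.16, 0.2))
  # the removed set has size 5, leaving 10 sized filters
  expect_length(setdiff(full$sized_filters, red$sized_filters), 5L)
  expect_length(red$sized_filters, 10L)

  nm <- bank_channel_names(full)
  expect_length(nm, 173L)
  expect_false(anyDuplicated(nm) > 0)

  expect_error(filter_bank_config(sizes_px = c(3, 2)), class = "fd_value_error")
  expect_error(filter_bank_config(gabor_frequencies = c(0.6)),
               class = "fd_value_error")
})

test_that("channel-count identity holds for arbitrary configurations", {
  set.seed(4)
  filters <- eval(formals(filter_bank_config)$sized_filters,
                  asNamespace("focidetect"))
  for (rep in 1:6) {
    cfg <- filter_bank_config(
      sized_filters = sample(filters, sample(1:15, 1)),
      sizes_px = sort(sample(2:12, sample(1:4, 1))),
      gabor_frequencies = sort(runif(sample(1:3, 1), 0.05, 0.45)),
      include_scharr = runif(1) > 0.5,
      include_raw = runif(1) > 0.5)
    closed <- length(cfg$sized_filters) * length(cfg$sizes_px) +
      length(cfg$gabor_frequencies) + cfg$include_scharr + 1L + cfg$include_raw
    expect_equal(n_bank_channels(cfg), closed)
    expect_length(bank_channel_names(cfg), closed)
    stk <- apply_bank(matrix(runif(40 * 40), 40, 40), cfg)
    expect_equal(dim(stk)[3], closed)
    expect_true(all(is.finite(stk)))
  }
})

test_that("derivative-type channels vanish on a constant image", {
  px <- matrix(0.4, 48, 48)
  cfg <- filter_bank_config(sized_filters = c("gradient", "entropy", "tophat"),
                            sizes_px = c(3L, 8L),
                            gabor_frequencies = 0.1)
  stk <- apply_bank(px, cfg)
  nm <- attr(stk, "channel_names")
  for (ch in c("gradient_s3", "gradient_s8", "entropy_s3", "entropy_s8",
               "tophat_s3", "tophat_s8", "scharr"))
    expect_equal(max(abs(stk[, , which(nm == ch)])), 0,
                 info = ch, tolerance = 1e-12)
})

test_that("maximum filter spreads a bright pixel over its disk footprint", {
  px <- matrix(0, 21, 21)
  px[11, 11] <- 1
  out <- sized_filter(px, "maximum", 3)
  expect_equal(out, oracle_disk_max(px, 3), tolerance = 1e-12)
  # footprint is the radius-3 disk: 29 pixels lit
  expect_equal(sum(out > 0.5), sum(disk_mask(21, 21, 11, 11, 3)))
})

test_that("rank filters are local: a pixel edit cannot act beyond its radius", {
  set.seed(9)
  px <- matrix(runif(40 * 40), 40, 40)
  px2 <- px
  px2[20, 20] <- 1
  for (f in c("maximum", "minimum", "median", "modal", "auto_level")) {
    for (s in c(2L, 5L)) {
      d <- abs(sized_filter(px, f, s) - sized_filter(px2, f, s))
      dist <- sqrt(outer((1:40 - 20)^2, (1:40 - 20)^2, "+"))
      expect_equal(max(d[dist > s + 0.5]), 0, info = sprintf("%s s=%d", f, s))
    }
  }
})

test_that("apply_bank is deterministic and rejects undersized images", {
  px <- matrix(runif(30 * 30), 30, 30)
  cfg <- filter_bank_config(sized_filters = c("mean", "entropy"),
                            sizes_px = c(2L, 4L), gabor_frequencies = 0.1)
  expect_identical(apply_bank(px, cfg), apply_bank(px, cfg))
  expect_error(apply_bank(matrix(runif(64), 8, 8), full_bank_config()),
               class = "fd_size_error")
})

test_that("anisotropy scores blobs low and lines high", {
  expect_equal(max(anisotropy_filter(matrix(0.3, 30, 30), 4)), 0)

  line <- matrix(0, 41, 41); line[21, 6:36] <- 1
  blob <- matrix(0, 41, 41)
  blob[disk_mask(41, 41, 21, 21, 8)] <- 1
  a_line <- anisotropy_filter(gaussian_blur(line, 1), 4)
  a_blob <- anisotropy_filter(gaussian_blur(blob, 1), 4)
  # structure-tensor oracle intuition: interior line pixels are strongly
  # oriented, disk interiors are not
  expect_gt(a_line[21, 21], a_blob[21, 21] + 0.3)
  expect_true(all(a_line >= 0 & a_line <= 1))

  # 90-degree rotation equivariance
  a_rot <- anisotropy_filter(t(gaussian_blur(line, 1))[41:1, ], 4)
  # tolerance covers moving-sum accumulation-order effects
  expect_lt(max(abs(a_rot - t(a_line)[41:1, ])), 1e-5)

  expect_error(anisotropy_filter(line, 1), class = "fd_value_error")
})
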