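test_that("scenes are seeded, bounded and honest about their truth", {
  cfg <- small_scene_cfg(41)
  sc <- generate_scene(cfg)
  sc2 <- generate_scene(cfg)
  expect_identical(sc$foci$pixels, sc2$foci$pixels)        # bit-identical
  expect_identical(sc$truth, sc2$truth)

  expect_true(all(sc$foci$pixels >= 0 & sc$foci$pixels <= 1))
  expect_true(all(sc$nuclear$pixels >= 0 & sc$nuclear$pixels <= 1))

  # every foci pixel lies inside a nucleus; counts match center lists
  expect_true(all(sc$truth$nucleus_label_mask[sc$truth$foci_mask] > 0))
  expect_equal(sc$truth$foci_count,
               vapply(sc$truth$foci_centers, nrow, integer(1)))

  # zero-mean config: empty truth
  cfg0 <- small_scene_cfg(42)
  cfg0$foci_per_nucleus_mean <- 0
  sc0 <- generate_scene(cfg0)
  expect_equal(sum(sc0$truth$foci_mask), 0)
  expect_equal(sum(sc0$truth$foci_count), 0)

  # impossible placement errors out
  crowded <- scene_config(image_size_px = c(64L, 64L), n_nuclei = 30L,
                          nucleus_radius_px = 14, seed = 1)
  expect_error(generate_scene(crowded), class = "fd_placement_error")
})

test_that("per-nucleus focus counts follow the configured Poisson law", {
  # sampler at scale: 10000 nuclei at mean 5, within 3 standard errors
  counts <- focidetect:::draw_focus_counts(10000, 5, seed = 43)
  se <- sqrt(5 / 10000)
  expect_lt(abs(mean(counts) - 5), 3 * se)
  expect_lt(abs(var(counts) - 5) / 5, 0.1)

  # through the scene path (counts can only be reduced by the bounded
  # separation retries, which are rare at these densities)
  total <- 0; n_nuc <- 0
  for (s in 1:6) {
    sc <- generate_scene(scene_config(seed = 500 + s))
    total <- total + sum(sc$truth$foci_count)
    n_nuc <- n_nuc + max(sc$truth$nucleus_label_mask)
  }
  mean_scene <- total / n_nuc
  expect_lt(abs(mean_scene - 8), 3 * sqrt(8 / n_nuc) + 0.25)
})

test_that("regime mixtures follow largest-remainder rounding", {
  scenes <- generate_training_set(9, cfg_base = scene_config(seed = 9,
                                                             n_nuclei = 0))
  reg <- attr(scenes, "regimes")
  expect_equal(sort(table(reg), decreasing = TRUE),
               sort(table(rep(c("good", "noisy", "halos"), c(6, 2, 1))),
                    decreasing = TRUE), ignore_attr = TRUE)
  expect_equal(unname(table(factor(reg, c("good", "noisy", "artefacts",
                                          "halos", "apoptotic")))),
               c(6L, 2L, 0L, 1L, 0L), ignore_attr = TRUE)

  one <- generate_training_set(1, mix = c(good = 1),
                               cfg_base = scene_config(seed = 2, n_nuclei = 0))
  expect_equal(attr(one, "regimes"), "good")

  expect_error(generate_training_set(3, mix = c(good = 0.5, noisy = 0.3)),
               class = "fd_value_error")
  expect_error(generate_training_set(3, mix = c(bogus = 1)),
               class = "fd_value_error")
})

test_that("regime modifiers change the image but never the truth contract", {
  base <- small_scene_cfg(77)
  for (reg in c("noisy", "artefacts", "halos", "apoptotic")) {
    cfg <- base; cfg$regime <- reg
    sc <- generate_scene(cfg)
    expect_true(all(sc$truth$nucleus_label_mask[sc$truth$foci_mask] > 0))
    expect_equal(sc$truth$foci_count,
                 vapply(sc$truth$foci_centers, nrow, integer(1)))
  }
  # noisy regime raises background
  good <- generate_scene(base)
  noisy_cfg <- base; noisy_cfg$regime <- "noisy"
  noisy <- generate_scene(noisy_cfg)
  expect_gt(median(noisy$foci$pixels[noisy$truth$nucleus_label_mask == 0]),
            median(good$foci$pixels[good$truth$nucleus_label_mask == 0]))
})

test_that("planted centers are recovered from the noiseless truth mask", {
  for (s in c(1, 13)) {
    sc <- generate_scene(scene_config(seed = s))
    fs <- detect_centers(label_mask(sc$truth$foci_mask))
    tc <- do.call(rbind, sc$truth$foci_centers)
    expect_equal(nrow(fs$centers), nrow(tc))
    for (i in seq_len(nrow(tc))) {
      d <- sqrt((fs$centers[, 1] - tc[i, 1])^2 +
                (fs$centers[, 2] - tc[i, 2])^2)
      expect_lt(min(d), 1.5)
    }
  }
})
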