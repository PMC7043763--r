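test_that("every base model separates proportion-separated Gaussian classes", {
  d <- toy_gaussians()
  y <- d$labels
  for (m in c("MLP", "SVM", "cNB", "RF")) {
    mod <- train_pixel_model(classifier_spec(m, seed = 5), d)
    pred <- vote(predict_pixel_prob(mod, d$features), "soft")
    f1 <- 2 * sum(pred & y) / (2 * sum(pred & y) + sum(pred & !y) + sum(!pred & y))
    expect_gte(f1, 0.99)
  }
})

test_that("degenerate training inputs are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(train_pixel_model(classifier_spec("MLP"),
                                 labeled_pixel_set(X, rep(FALSE, 10))),
               class = "fd_training_error")
  X[1] <- NA
  expect_error(train_pixel_model(classifier_spec("MLP"),
                                 labeled_pixel_set(X, rep(c(TRUE, FALSE), 5))),
               class = "fd_value_error")
  expect_error(classifier_spec(character(0)), class = "fd_value_error")
  expect_error(labeled_pixel_set(matrix(0, 3, 2), c(TRUE, FALSE)),
               class = "fd_shape_error")
})

test_that("vote implements soft mean and hard strict-majority semantics", {
  # [0.9, 0.2] soft: mean 0.55 -> positive
  expect_true(vote(list(0.9, 0.2), "soft"))
  # hard tie -> negative
  expect_false(vote(list(1, 0), "hard"))
  # single model: vote equals its own prediction
  p <- c(0.2, 0.7, 0.51)
  expect_equal(vote(list(p), "soft"), p > 0.5)
  expect_equal(vote(list(p), "hard"), p > 0.5)
  expect_error(vote(list()), class = "fd_value_error")
  expect_error(vote(list(c(1, 0), 1)), class = "fd_shape_error")

  # unanimity is never overturned; hard 2-model vote is AND
  set.seed(6)
  for (rep in 1:20) {
    k <- sample(1:4, 1)
    probs <- replicate(k, runif(30), simplify = FALSE)
    unanimous_pos <- Reduce(`&`, lapply(probs, function(p) p > 0.5))
    unanimous_neg <- Reduce(`&`, lapply(probs, function(p) p <= 0.5))
    for (rule in c("soft", "hard")) {
      v <- vote(probs, rule)
      expect_true(all(v[unanimous_pos]))
      expect_true(all(!v[unanimous_neg]))
    }
  }
  a <- runif(50); b <- runif(50)
  expect_equal(vote(list(a, b), "hard"), (a > 0.5) & (b > 0.5))
})

test_that("one training pass supports all 15 voting combinations", {
  d <- toy_gaussians(n_per_class = 250)
  mod <- train_pixel_model(classifier_spec(c("MLP", "SVM", "cNB", "RF"),
                                           seed = 7), d)
  expect_length(mod$components, 4L)
  members <- names(mod$components)
  combos <- unlist(lapply(1:4, function(k)
    utils::combn(members, k, simplify = FALSE)), recursive = FALSE)
  expect_length(combos, 15L)
  y <- d$labels
  for (cmb in combos) {
    pred <- vote(predict_pixel_prob(mod, d$features, models = cmb), "soft")
    f1 <- 2 * sum(pred & y) / (2 * sum(pred & y) + sum(pred & !y) + sum(!pred & y))
    expect_gte(f1, 0.95)
  }
})

test_that("training is deterministic given the seed and survives a save/load", {
  d <- toy_gaussians(n_per_class = 200)
  spec <- classifier_spec(c("MLP", "RF"), seed = 99, rf_trees = 25L,
                          mlp_max_epochs = 40L)
  m1 <- train_pixel_model(spec, d)
  m2 <- train_pixel_model(spec, d)
  expect_identical(predict_pixel_prob(m1, d$features),
                   predict_pixel_prob(m2, d$features))

  p <- withr::local_tempfile(fileext = ".json")
  save_model(m1, p)
  m3 <- load_model(p)
  expect_equal(predict_pixel_prob(m3, d$features),
               predict_pixel_prob(m1, d$features), tolerance = 1e-12)
})

test_that("an MLP trained on imbalanced synthetic scenes clears MCC 0.4", {
  # >90% of within-nucleus pixels are negatives in these scenes
  train <- lapply(c(301, 302, 303), function(s)
    generate_scene(small_scene_cfg(s)))
  test <- generate_scene(small_scene_cfg(399))
  # constant channels (if any) are legitimately dropped with a warning
  ts <- suppressWarnings(build_training_set(lapply(train, `[[`, "foci"),
                           lapply(train, function(s) s$truth$foci_mask),
                           nucleus_masks = lapply(train, function(s)
                             s$truth$nucleus_label_mask),
                           bank_cfg = reduced_bank_config(),
                           pixels_per_image = 8000L, seed = 77))
  expect_lt(mean(ts$labels), 0.35)
  mod <- train_pixel_model(classifier_spec("MLP", seed = 78,
                                           mlp_max_epochs = 120L), ts)
  pm <- predict_mask(mod, test$foci)
  inside <- test$truth$nucleus_label_mask > 0
  tally <- pixel_tally(pm$pixels & inside, test$truth$foci_mask)
  expect_gt(compute_metrics(tally)$mcc, 0.4)

  # whole-image imbalance check: >90% true negatives
  expect_gt(mean(!test$truth$foci_mask), 0.9)

  # model trained on scenes applied to a blank image -> empty mask
  blank <- channel_image(matrix(0, 128, 128), pixel_size_um = 0.1172)
  expect_equal(sum(predict_mask(mod, blank)$pixels), 0)
})
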