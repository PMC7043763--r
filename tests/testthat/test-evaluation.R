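test_that("pixel_tally counts match an exhaustive per-pixel loop", {
  set.seed(31)
  a <- matrix(runif(400) > 0.7, 20, 20)
  b <- matrix(runif(400) > 0.7, 20, 20)
  tal <- pixel_tally(a, b)
  tp <- fp <- fn <- tn <- 0
  for (i in 1:20) for (j in 1:20) {
    if (a[i, j] && b[i, j]) tp <- tp + 1
    else if (a[i, j]) fp <- fp + 1
    else if (b[i, j]) fn <- fn + 1
    else tn <- tn + 1
  }
  expect_equal(tal$tp, tp); expect_equal(tal$fp, fp)
  expect_equal(tal$fn, fn); expect_equal(tal$tn, tn)
  expect_equal(tal$tp + tal$fp + tal$fn + tal$tn, 400)

  # identical masks; all-negative prediction
  t2 <- pixel_tally(b, b)
  expect_equal(t2$fp + t2$fn, 0)
  expect_equal(t2$tp, sum(b))
  t3 <- pixel_tally(matrix(FALSE, 20, 20), b)
  expect_equal(t3$fn, sum(b)); expect_equal(t3$tp, 0)

  expect_error(pixel_tally(a, b[1:10, ]), class = "fd_shape_error")
})

test_that("match_centers applies the 5 px rule one-to-one", {
  # distance 4 <= 5 -> matched
  tal <- match_centers(rbind(c(10, 10)), rbind(c(10, 14)), 5)
  expect_equal(c(tal$tp, tal$fp, tal$fn), c(1, 0, 0))
  # distance 6 -> both unmatched
  tal <- match_centers(rbind(c(10, 10)), rbind(c(10, 16)), 5)
  expect_equal(c(tal$tp, tal$fp, tal$fn), c(0, 1, 1))
  # empties allowed
  tal <- match_centers(matrix(numeric(0), 0, 2), rbind(c(1, 1)), 5)
  expect_equal(c(tal$tp, tal$fp, tal$fn), c(0, 0, 1))

  # greedy tally equals exhaustive optimal assignment on random layouts
  set.seed(32)
  for (rep in 1:30) {
    na <- sample(0:6, 1); nm <- sample(0:5, 1)
    auto <- matrix(runif(2 * na, 0, 30), ncol = 2)
    manual <- matrix(runif(2 * nm, 0, 30), ncol = 2)
    tal <- match_centers(auto, manual, 5)
    best <- oracle_max_matching(auto, manual, 5)
    expect_equal(tal$tp, best)
    expect_equal(tal$tp + tal$fp, na)
    expect_equal(tal$tp + tal$fn, nm)
    expect_lte(tal$tp, min(na, nm))
  }
})

test_that("compute_metrics reproduces the published object-wise table", {
  t4 <- table4_rows(); t3 <- table3_rows()
  for (m in rownames(t4)) {
    rep <- compute_metrics(detection_tally(tp = t4[m, "tp"], fp = t4[m, "fp"],
                                           fn = t4[m, "fn"]))
    expect_equal(round(rep$sensitivity, 3), unname(t3[m, "sensitivity"]), info = m)
    expect_equal(round(rep$ppv, 3), unname(t3[m, "ppv"]), info = m)
    expect_equal(round(rep$fnr, 3), unname(t3[m, "fnr"]), info = m)
    expect_equal(round(rep$f1, 3), unname(t3[m, "f1"]), info = m)
    expect_null(rep$mcc)
  }

  # pixel-wise MCC from published confusion counts
  t2 <- table2_rows()
  rep <- compute_metrics(detection_tally(tp = t2["MLP", "tp"],
                                         fp = t2["MLP", "fp"],
                                         fn = t2["MLP", "fn"],
                                         tn = t2["MLP", "tn"]))
  expect_equal(round(rep$mcc, 3), 0.787)

  # perfect detection
  perfect <- compute_metrics(detection_tally(tp = 7, fp = 0, fn = 0))
  expect_equal(c(perfect$sensitivity, perfect$ppv, perfect$f1), c(1, 1, 1))
  expect_equal(perfect$fnr, 0)

  # zero denominators are flagged, never silent zeros
  z <- compute_metrics(detection_tally(0, 0, 0, 0))
  expect_true(all(c("sensitivity", "ppv", "fnr", "f1", "mcc") %in% z$undefined))
  expect_true(is.na(z$f1))
})

test_that("sensitivity + FNR = 1 and metric ranges hold on random tallies", {
  set.seed(33)
  for (rep in 1:40) {
    tal <- detection_tally(tp = sample(1:500, 1), fp = sample(0:200, 1),
                           fn = sample(0:200, 1), tn = sample(0:5000, 1))
    r <- compute_metrics(tal)
    expect_equal(r$sensitivity + r$fnr, 1)
    expect_true(r$f1 >= 0 && r$f1 <= 1)
    expect_true(r$ppv >= 0 && r$ppv <= 1)
    if (!is.na(r$mcc)) expect_true(r$mcc >= -1 && r$mcc <= 1)
  }
  # mcc = 1 iff no errors with both classes present
  expect_equal(compute_metrics(detection_tally(5, 0, 0, 10))$mcc, 1)
})

test_that("bootstrap CIs behave at the degenerate and enumerable limits", {
  # identical per-nucleus tallies: zero resampling variance
  tal <- detection_tally(tp = 10, fp = 2, fn = 3)
  r <- bootstrap_ci(list(tal, tal, tal, tal), "f1",
                    bootstrap_config(n_reps = 200, seed = 4))
  expect_equal(r$ci_low, r$point)
  expect_equal(r$ci_high, r$point)

  # 3 nuclei: compare against exhaustive enumeration of all 27 resamples
  tallies <- list(detection_tally(8, 1, 2), detection_tally(3, 4, 1),
                  detection_tally(6, 0, 5))
  pool_f1 <- function(idx) {
    tp <- sum(sapply(tallies[idx], `[[`, "tp"))
    fp <- sum(sapply(tallies[idx], `[[`, "fp"))
    fn <- sum(sapply(tallies[idx], `[[`, "fn"))
    2 * tp / (2 * tp + fp + fn)
  }
  grid <- expand.grid(1:3, 1:3, 1:3)
  exact <- apply(grid, 1, function(g) pool_f1(as.integer(g)))
  # inverse CDF of the 27-atom resampling distribution
  exact_ci <- unname(quantile(exact, c(0.025, 0.975), type = 1))
  r <- bootstrap_ci(tallies, "f1", bootstrap_config(n_reps = 8000, seed = 5))
  expect_equal(r$point, pool_f1(1:3))
  expect_lt(abs(r$ci_low - exact_ci[1]), 0.02)
  expect_lt(abs(r$ci_high - exact_ci[2]), 0.02)

  # determinism
  r2 <- bootstrap_ci(tallies, "f1", bootstrap_config(n_reps = 8000, seed = 5))
  expect_identical(r[c("ci_low", "ci_high")], r2[c("ci_low", "ci_high")])

  # basic interval is the reflection of the percentile interval
  rb <- bootstrap_ci(tallies, "f1",
                     bootstrap_config(n_reps = 2000, seed = 6, method = "basic"))
  rp <- bootstrap_ci(tallies, "f1",
                     bootstrap_config(n_reps = 2000, seed = 6))
  expect_equal(rb$ci_low, 2 * rp$point - rp$ci_high)
  expect_equal(rb$ci_high, 2 * rp$point - rp$ci_low)

  # undefined metric on many resamples warns
  sparse <- list(detection_tally(0, 0, 4), detection_tally(2, 1, 0))
  expect_warning(bootstrap_ci(sparse, "ppv",
                              bootstrap_config(n_reps = 400, seed = 7)),
                 "undefined")
  expect_error(bootstrap_ci(list(), "f1"), class = "fd_value_error")
})

test_that("ci_significance is disjointness of intervals", {
  ci <- function(lo, hi) list(ci_low = lo, ci_high = hi)
  expect_true(ci_significance(ci(0.80, 0.85), ci(0.87, 0.91)))
  expect_false(ci_significance(ci(0.80, 0.88), ci(0.87, 0.91)))
  expect_false(ci_significance(ci(0.80, 0.88), ci(0.80, 0.88)))
  expect_true(ci_significance(ci(0.87, 0.91), ci(0.80, 0.85)))
  expect_error(ci_significance(ci(0.1, NA), ci(0, 1)), class = "fd_value_error")
})
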