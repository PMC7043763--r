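# Scoring of automatic detections against manual labels: pixel-wise
# confusion counts (F1, MCC), object-wise center matching within a fixed
# radius (sensitivity, PPV, FNR, F1), bootstrap confidence intervals over
# nuclei, and CI-overlap significance calls.

#' Confusion-count container
#'
#' @param tp,fp,fn non-negative counts.
#' @param tn non-negative count, or `NULL` for object-wise tallies (no
#'   true-negative notion exists for center matching).
#' @return an `fd_tally`.
#' @export
detection_tally <- function(tp, fp, fn, tn = NULL) {
  for (v in list(tp, fp, fn)) if (!is.numeric(v) || length(v) != 1 || v < 0)
    fd_stop("counts must be non-negative scalars", "fd_value_error")
  if (!is.null(tn) && (!is.numeric(tn) || tn < 0))
    fd_stop("tn must be non-negative", "fd_value_error")
  structure(list(tp = as.numeric(tp), fp = as.numeric(fp),
                 fn = as.numeric(fn),
                 tn = if (is.null(tn)) NULL else as.numeric(tn)),
            class = "fd_tally")
}

.pool_tallies <- function(tallies) {
  tp <- sum(vapply(tallies, `[[`, numeric(1), "tp"))
  fp <- sum(vapply(tallies, `[[`, numeric(1), "fp"))
  fn <- sum(vapply(tallies, `[[`, numeric(1), "fn"))
  tns <- lapply(tallies, `[[`, "tn")
  tn <- if (any(vapply(tns, is.null, logical(1)))) NULL else sum(unlist(tns))
  detection_tally(tp, fp, fn, tn)
}

#' Pixel-wise confusion counts
#'
#' @param pred,truth [label_mask()]s or logical matrices of equal
#'   dimensions.
#' @param roi optional `fd_nucleus_roi`; counts are restricted to its mask
#'   (tp+fp+fn+tn then equals the ROI pixel count).
#' @return an `fd_tally` with `tn` present.
#' @export
pixel_tally <- function(pred, truth, roi = NULL) {
  p <- .as_binary_mask(pred)
  t <- .as_binary_mask(truth)
  if (!all(dim(p) == dim(t)))
    fd_stop("mask dimensions differ", "fd_shape_error")
  if (!is.null(roi)) {
    if (!all(dim(roi$mask) == dim(p)))
      fd_stop("ROI dimensions differ from masks", "fd_shape_error")
    p <- p[roi$mask]; t <- t[roi$mask]
  }
  detection_tally(tp = sum(p & t), fp = sum(p & !t),
                  fn = sum(!p & t), tn = sum(!p & !t))
}

#' Match automatic and manual focus centers
#'
#' One-to-one matching: candidate pairs with Euclidean distance <= radius
#' are matched greedily by ascending distance (ties broken by lowest
#' (row, col) of the automatic then the manual center).  Matched pairs are
#' true positives, unmatched automatic centers false positives, unmatched
#' manual centers false negatives; no true-negative count exists.
#'
#' @param auto,manual numeric matrices with columns (row, col); zero rows
#'   allowed.
#' @param radius_px matching radius (default 5 px, about 0.6 focus
#'   diameters).
#' @return an `fd_tally` without `tn`.
#' @export
match_centers <- function(auto, manual, radius_px = 5) {
  fd_assert_scalar_pos(radius_px, "radius_px")
  auto <- matrix(as.numeric(auto), ncol = 2)
  manual <- matrix(as.numeric(manual), ncol = 2)
  if (any(!is.finite(auto)) || any(!is.finite(manual)))
    fd_stop("center coordinates must be finite", "fd_value_error")
  na <- nrow(auto); nm <- nrow(manual)
  if (na == 0 || nm == 0)
    return(detection_tally(tp = 0, fp = na, fn = nm))
  d <- sqrt(outer(auto[, 1], manual[, 1], "-")^2 +
            outer(auto[, 2], manual[, 2], "-")^2)
  cand <- which(d <= radius_px, arr.ind = TRUE)
  if (nrow(cand)) {
    ord <- order(d[cand], auto[cand[, 1], 1], auto[cand[, 1], 2],
                 manual[cand[, 2], 1], manual[cand[, 2], 2])
    cand <- cand[ord, , drop = FALSE]
  }
  used_a <- logical(na); used_m <- logical(nm)
  tp <- 0
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_a[i] && !used_m[j]) {
      used_a[i] <- used_m[j] <- TRUE
      tp <- tp + 1
    }
  }
  detection_tally(tp = tp, fp = na - tp, fn = nm - tp)
}

#' Derived detection metrics from a tally
#'
#' sensitivity = tp/(tp+fn); ppv = tp/(tp+fp); fnr = fn/(tp+fn);
#' f1 = 2tp/(2tp+fp+fn); mcc (pixel-wise tallies only) =
#' (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn)).  A metric whose
#' denominator is zero is reported as `NA` and named in `undefined`,
#' never silently set to 0.
#'
#' @param tally an `fd_tally`.
#' @return an `fd_metric_report`: list with sensitivity, ppv, fnr, f1,
#'   mcc (NULL when tn is absent) and `undefined` (character vector).
#' @export
compute_metrics <- function(tally) {
  if (!inherits(tally, "fd_tally"))
    fd_stop("tally must be an fd_tally", "fd_value_error")
  tp <- tally$tp; fp <- tally$fp; fn <- tally$fn; tn <- tally$tn
  undefined <- character(0)
  div <- function(num, den, name) {
    if (den <= 0) { undefined <<- c(undefined, name); return(NA_real_) }
    num / den
  }
  sens <- div(tp, tp + fn, "sensitivity")
  ppv <- div(tp, tp + fp, "ppv")
  fnr <- div(fn, tp + fn, "fnr")
  f1 <- div(2 * tp, 2 * tp + fp + fn, "f1")
  mcc <- NULL
  if (!is.null(tn)) {
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den <= 0) {
      undefined <- c(undefined, "mcc")
      mcc <- NA_real_
    } else mcc <- (tp * tn - fp * fn) / den
  }
  structure(list(sensitivity = sens, ppv = ppv, fnr = fnr, f1 = f1,
                 mcc = mcc, tally = tally, undefined = undefined),
            class = "fd_metric_report")
}

#' Bootstrap configuration
#'
#' @param n_reps bootstrap resamples (default 1000 per experimental
#'   group).
#' @param ci_level confidence level (default 0.95).
#' @param method `"percentile"` (empirical percentile interval) or
#'   `"basic"` (reflected interval `2*point - percentile`).
#' @param seed integer seed.
#' @return an `fd_bootstrap_config`.
#' @export
bootstrap_config <- function(n_reps = 1000L, ci_level = 0.95,
                             method = c("percentile", "basic"), seed = 1L) {
  method <- match.arg(method)
  fd_assert_scalar_pos(n_reps, "n_reps")
  if (ci_level <= 0 || ci_level >= 1)
    fd_stop("ci_level must lie in (0, 1)", "fd_value_error")
  structure(list(n_reps = as.integer(n_reps), ci_level = ci_level,
                 method = method, seed = as.integer(seed)),
            class = "fd_bootstrap_config")
}

.metric_from_pooled <- function(tallies, metric) {
  rep <- compute_metrics(.pool_tallies(tallies))
  v <- rep[[metric]]
  if (is.null(v)) NA_real_ else v
}

#' Bootstrap confidence interval of a pooled detection metric
#'
#' Nuclei (their per-nucleus tallies) are treated as independent units and
#' resampled with replacement; the metric is recomputed on each resample's
#' pooled tally.  The point estimate is the metric on the original pooled
#' tally.  Resamples on which the metric is undefined are dropped, with a
#' warning when they exceed 20%.
#'
#' @param per_nucleus_tallies list of `fd_tally` (one per nucleus).
#' @param metric one of `"sensitivity"`, `"ppv"`, `"fnr"`, `"f1"`,
#'   `"mcc"`.
#' @param cfg a [bootstrap_config()].
#' @return list with `point`, `ci_low`, `ci_high`, `metric`, `method`,
#'   `n_nuclei`, `n_reps`.
#' @export
bootstrap_ci <- function(per_nucleus_tallies, metric,
                         cfg = bootstrap_config()) {
  if (length(per_nucleus_tallies) < 1)
    fd_stop("need at least one nucleus", "fd_value_error")
  metric <- match.arg(metric, c("sensitivity", "ppv", "fnr", "f1", "mcc"))
  point <- .metric_from_pooled(per_nucleus_tallies, metric)
  if (is.na(point))
    fd_stop(sprintf("metric %s is undefined on the pooled tally", metric),
            "fd_value_error")
  n <- length(per_nucleus_tallies)
  stats <- with_seed(cfg$seed, vapply(seq_len(cfg$n_reps), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    .metric_from_pooled(per_nucleus_tallies[idx], metric)
  }, numeric(1)))
  bad <- sum(is.na(stats))
  if (bad >= 0.2 * cfg$n_reps)
    warning(sprintf("metric undefined on %d of %d resamples", bad, cfg$n_reps))
  stats <- stats[!is.na(stats)]
  a <- (1 - cfg$ci_level) / 2
  qs <- unname(quantile(stats, c(a, 1 - a), type = 7))
  ci <- if (cfg$method == "percentile") qs else
    c(2 * point - qs[2], 2 * point - qs[1])
  list(point = point, ci_low = ci[1], ci_high = ci[2], metric = metric,
       method = cfg$method, n_nuclei = n, n_reps = cfg$n_reps)
}

#' Significance by confidence-interval overlap
#'
#' Two groups are called significantly different when their confidence
#' intervals are disjoint.
#'
#' @param a,b results of [bootstrap_ci()] (or any lists with `ci_low`,
#'   `ci_high`).
#' @return TRUE iff the intervals do not overlap.
#' @export
ci_significance <- function(a, b) {
  for (x in list(a, b))
    if (is.null(x$ci_low) || is.null(x$ci_high) ||
        is.na(x$ci_low) || is.na(x$ci_high))
      fd_stop("both arguments need confidence intervals", "fd_value_error")
  a$ci_high < b$ci_low || b$ci_high < a$ci_low
}
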