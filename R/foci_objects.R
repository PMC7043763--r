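# From binary foci masks to countable foci: size filtering, circular-Hough
# center detection and overlap splitting.

#' Post-processing parameters
#'
#' The default Hough radii bracket the typical focus radius (~4 px at the
#' training pixel scale, i.e. a diameter of ~8 px); the 16 px area floor is
#' applied at the training pixel scale, after any magnification rescaling.
#'
#' @param min_object_area_px objects with area strictly below this are
#'   removed (default 16).
#' @param match_radius_px center-matching radius used downstream
#'   (default 5 px, about 0.6 focus diameters).
#' @param hough_radii_px increasing circle radii tried by the Hough split.
#' @param hough_peak_threshold accumulator fraction of a complete ring
#'   required to accept a center (in (0,1)).
#' @return an `fd_postprocess_config`.
#' @export
postprocess_config <- function(min_object_area_px = 16L,
                               match_radius_px = 5,
                               hough_radii_px = c(3L, 4L, 5L, 6L),
                               hough_peak_threshold = 0.5) {
  if (min_object_area_px < 0)
    fd_stop("min_object_area_px must be >= 0", "fd_value_error")
  fd_assert_scalar_pos(match_radius_px, "match_radius_px")
  if (length(hough_radii_px) == 0 || any(hough_radii_px < 1) ||
      any(diff(hough_radii_px) <= 0))
    fd_stop("hough_radii_px must be non-empty, positive, increasing",
            "fd_value_error")
  if (hough_peak_threshold <= 0 || hough_peak_threshold >= 1)
    fd_stop("hough_peak_threshold must lie in (0, 1)", "fd_value_error")
  structure(list(min_object_area_px = as.integer(min_object_area_px),
                 match_radius_px = match_radius_px,
                 hough_radii_px = as.integer(hough_radii_px),
                 hough_peak_threshold = hough_peak_threshold),
            class = "fd_postprocess_config")
}

.as_binary_mask <- function(mask) {
  px <- if (inherits(mask, "fd_label_mask")) mask$pixels else mask
  if (!is.logical(px)) px <- px > 0
  px
}

#' Remove small objects from a mask
#'
#' Connected components (8-connectivity) with area strictly smaller than
#' `min_area_px` are set to background; all other pixels are untouched.
#'
#' @param mask an [label_mask()] or logical matrix.
#' @param min_area_px area floor in pixels.
#' @return an [label_mask()] (logical).
#' @export
size_filter <- function(mask, min_area_px = 16L) {
  px <- .as_binary_mask(mask)
  meta <- if (inherits(mask, "fd_label_mask")) mask$meta else NULL
  if (min_area_px > 0 && any(px)) {
    lab <- cpp_label(px, 8L)
    areas <- tabulate(lab[lab > 0])
    drop <- which(areas < min_area_px)
    if (length(drop)) px[matrix(lab %in% drop, nrow(px))] <- FALSE
  }
  label_mask(px, meta)
}

# Peak height an ideal isolated lattice disk of radius r reaches in its own
# accumulator: used to normalize for discretization (1.0 = perfect disk).
.hough_calibration <- function(radii) {
  vapply(radii, function(r) {
    n <- 2L * r + 7L
    disk <- outer((seq_len(n) - (r + 4))^2,
                           (seq_len(n) - (r + 4))^2, "+") <= r^2
    acc <- cpp_hough_circle(.component_edges(disk), r)
    max(acc)
  }, numeric(1))
}

.component_edges <- function(m) {
  H <- nrow(m); W <- ncol(m)
  up <- rbind(FALSE, m[-H, , drop = FALSE])
  dn <- rbind(m[-1, , drop = FALSE], FALSE)
  lf <- cbind(FALSE, m[, -W, drop = FALSE])
  rt <- cbind(m[, -1, drop = FALSE], FALSE)
  m & !(up & dn & lf & rt)
}

#' Detect focus centers with circular-Hough splitting
#'
#' Per connected component, circles of the configured radii are accumulated
#' over the component's edge pixels; each radius is normalized by the peak
#' an ideal isolated lattice disk of that radius achieves, so 1.0 means a
#' perfect disk.  Peaks reaching `hough_peak_threshold` become centers
#' after scale-aware non-maximum suppression (an accepted peak suppresses
#' weaker peaks within its best-fit radius, floored at the smallest
#' configured radius), so a merged blob of overlapping foci yields one
#' center per constituent circle.  Components yielding no peak contribute
#' their centroid.
#'
#' @param mask a size-filtered [label_mask()] or logical matrix.
#' @param foci_img optional [channel_image()] (unused by the geometric
#'   splitter; accepted for interface compatibility).
#' @param cfg a [postprocess_config()].
#' @return an `fd_foci_set`: list with `labels` (integer matrix), `centers`
#'   (n x 2 matrix of 1-based (row, col)), `center_label` (component id per
#'   center) and `area_px` (per-component areas).
#' @export
detect_centers <- function(mask, foci_img = NULL, cfg = postprocess_config()) {
  px <- .as_binary_mask(mask)
  lab <- cpp_label(px, 8L)
  n_comp <- max(lab)
  centers <- matrix(numeric(0), 0, 2)
  center_label <- integer(0)
  areas <- if (n_comp > 0) tabulate(lab[lab > 0], n_comp) else integer(0)
  if (n_comp > 0) {
    calib <- .hough_calibration(cfg$hough_radii_px)
    pad <- max(cfg$hough_radii_px) + 1L
    H <- nrow(px); W <- ncol(px)
    for (id in seq_len(n_comp)) {
      m <- lab == id
      rows <- range(which(rowSums(m) > 0))
      cols <- range(which(colSums(m) > 0))
      r0 <- max(1L, rows[1] - pad); r1 <- min(H, rows[2] + pad)
      c0 <- max(1L, cols[1] - pad); c1 <- min(W, cols[2] + pad)
      sub <- m[r0:r1, c0:c1, drop = FALSE]
      edges <- .component_edges(sub)
      acc <- matrix(0, nrow(sub), ncol(sub))
      rbest <- matrix(cfg$hough_radii_px[1], nrow(sub), ncol(sub))
      for (ri in seq_along(cfg$hough_radii_px)) {
        a1 <- cpp_hough_circle(edges, cfg$hough_radii_px[ri]) / calib[ri]
        upd <- a1 > acc
        rbest[upd] <- cfg$hough_radii_px[ri]
        acc <- pmax(acc, a1)
      }
      # candidates must be 8-neighborhood local maxima of the accumulator
      # (shoulder pixels on a peak's slope are not), then scale-aware
      # greedy non-maximum suppression: an accepted peak suppresses weaker
      # peaks within its own best-fit circle radius (floored at the
      # smallest configured radius)
      locmax <- matrix(TRUE, nrow(sub), ncol(sub))
      for (dy in -1:1) for (dx in -1:1) {
        if (dy == 0 && dx == 0) next
        H2 <- nrow(sub); W2 <- ncol(sub)
        ri2 <- pmin(pmax(seq_len(H2) + dy, 1), H2)
        ci2 <- pmin(pmax(seq_len(W2) + dx, 1), W2)
        locmax <- locmax & (acc >= acc[ri2, ci2, drop = FALSE])
      }
      cand <- which(sub & locmax & acc >= cfg$hough_peak_threshold,
                    arr.ind = TRUE)
      peaks <- matrix(integer(0), 0, 2)
      if (nrow(cand)) {
        v <- acc[cand]
        ord <- order(-v, cand[, 1], cand[, 2])
        cand <- cand[ord, , drop = FALSE]
        kept <- matrix(numeric(0), 0, 3)  # row, col, suppression radius
        for (k in seq_len(nrow(cand))) {
          y <- cand[k, 1]; x <- cand[k, 2]
          if (nrow(kept) == 0 ||
              all((kept[, 1] - y)^2 + (kept[, 2] - x)^2 > kept[, 3]^2)) {
            rs <- max(rbest[y, x], min(cfg$hough_radii_px))
            kept <- rbind(kept, c(y, x, rs))
          }
        }
        peaks <- kept[, 1:2, drop = FALSE] - 1  # 0-based like cpp_peak_coords
      }
      if (nrow(peaks) == 0) {
        idx <- which(sub, arr.ind = TRUE)
        ctr <- colMeans(idx)
        # snap the centroid into the component for non-convex shapes
        if (!sub[round(ctr[1]), round(ctr[2])]) {
          d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2
          ctr <- idx[which.min(d2), ]
        }
        cc <- matrix(c(ctr[1], ctr[2]), 1, 2)
      } else {
        cc <- cbind(peaks[, 1] + 1, peaks[, 2] + 1)
      }
      cc[, 1] <- cc[, 1] + r0 - 1
      cc[, 2] <- cc[, 2] + c0 - 1
      centers <- rbind(centers, cc)
      center_label <- c(center_label, rep(id, nrow(cc)))
    }
  }
  colnames(centers) <- c("row", "col")
  structure(list(labels = lab, centers = centers,
                 center_label = center_label, area_px = areas),
            class = "fd_foci_set")
}

#' Per-nucleus foci counts from a foci set
#' @param fociset an `fd_foci_set` from [detect_centers()].
#' @param rois list of `fd_nucleus_roi`.
#' @return data frame with columns `nucleus`, `n_foci`.
#' @export
count_foci_per_nucleus <- function(fociset, rois) {
  n <- vapply(rois, function(r) {
    if (nrow(fociset$centers) == 0) return(0L)
    ri <- pmin(pmax(round(fociset$centers[, 1]), 1), nrow(r$mask))
    ci <- pmin(pmax(round(fociset$centers[, 2]), 1), ncol(r$mask))
    sum(r$mask[cbind(ri, ci)])
  }, integer(1))
  data.frame(nucleus = vapply(rois, function(r) r$label_id, integer(1)),
             n_foci = n)
}
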