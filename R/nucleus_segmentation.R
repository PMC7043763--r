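# Nucleus detection in the DAPI channel: median filter -> CLAHE -> Otsu ->
# hole filling -> distance-transform watershed splitting of touching nuclei.

#' Segmentation parameters
#'
#' Defaults are tuned for 1388x1038 px fields with nuclei of roughly 100 px
#' diameter at the training magnification (0.1172 um/px); scale
#' `min_nucleus_area_px`, `peak_min_distance_px` and `median_radius_px`
#' when working at other pixel sizes.
#'
#' @param median_radius_px radius of the denoising median filter (disk).
#' @param clahe_clip CLAHE clip limit as a fraction of the tile pixel
#'   count, in (0, 1].
#' @param clahe_tile_px CLAHE tile edge length in pixels.
#' @param min_nucleus_area_px components smaller than this are discarded.
#' @param peak_min_distance_px minimum separation of watershed seed peaks
#'   in the distance transform.
#' @param exclude_border drop nuclei touching the image border
#'   (default FALSE: border nuclei are kept).
#' @return an `fd_segmentation_config` object.
#' @export
segmentation_config <- function(median_radius_px = 3L,
                                clahe_clip = 0.01,
                                clahe_tile_px = 128L,
                                min_nucleus_area_px = 500L,
                                peak_min_distance_px = 20,
                                exclude_border = FALSE) {
  fd_assert_scalar_pos(median_radius_px, "median_radius_px")
  if (!is.numeric(clahe_clip) || clahe_clip <= 0 || clahe_clip > 1)
    fd_stop("clahe_clip must lie in (0, 1]", "fd_value_error")
  fd_assert_scalar_pos(clahe_tile_px, "clahe_tile_px")
  if (min_nucleus_area_px < 0)
    fd_stop("min_nucleus_area_px must be >= 0", "fd_value_error")
  fd_assert_scalar_pos(peak_min_distance_px, "peak_min_distance_px")
  structure(list(median_radius_px = as.integer(median_radius_px),
                 clahe_clip = clahe_clip,
                 clahe_tile_px = as.integer(clahe_tile_px),
                 min_nucleus_area_px = as.integer(min_nucleus_area_px),
                 peak_min_distance_px = peak_min_distance_px,
                 exclude_border = isTRUE(exclude_border)),
            class = "fd_segmentation_config")
}

#' Otsu threshold of an image
#'
#' Picks, over a 256-bin histogram, the threshold maximizing between-class
#' variance.  Returned on the input intensity scale, strictly between the
#' minimum and maximum intensity.
#'
#' @param img a [channel_image()] or numeric matrix.
#' @return scalar threshold; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(img) {
  px <- if (inherits(img, "fd_channel_image")) img$pixels else img
  lo <- min(px); hi <- max(px)
  if (hi <= lo)
    fd_stop("Otsu threshold is undefined for a constant image",
            "fd_degenerate_error")
  nbins <- 256L
  bin <- pmin(nbins - 1L, as.integer((px - lo) / (hi - lo) * nbins))
  h <- tabulate(bin + 1L, nbins)
  n <- sum(h)
  levels <- seq_len(nbins) - 1
  w0 <- cumsum(h)                     # class 0: bins <= t
  m0 <- cumsum(h * levels)
  w1 <- n - w0
  mt <- m0[nbins]
  # between-class variance for thresholds after bin t (t = 0..254)
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins)
  bcv[valid] <- (mt * w0[valid] - n * m0[valid])^2 / (w0[valid] * w1[valid])
  t_bin <- which.max(bcv) - 1L        # last bin of the background class
  # strictly separating value: midpoint between the largest background-class
  # pixel and the smallest foreground-class pixel
  (max(px[bin <= t_bin]) + min(px[bin > t_bin])) / 2
}

.fill_holes <- function(mask) {
  inv <- !mask
  lab <- cpp_label(inv, 4L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  hole <- inv & !(lab %in% border)
  mask | matrix(hole, nrow(mask))
}

.roi_from_labels <- function(labels, min_area, exclude_border) {
  H <- nrow(labels); W <- ncol(labels)
  ids <- sort(unique(labels[labels > 0]))
  rois <- list()
  next_id <- 1L
  for (id in ids) {
    m <- labels == id
    area <- sum(m)
    if (area < min_area) next
    rows <- range(which(rowSums(m) > 0))
    cols <- range(which(colSums(m) > 0))
    if (exclude_border &&
        (rows[1] == 1 || cols[1] == 1 || rows[2] == H || cols[2] == W)) next
    rois[[next_id]] <- structure(
      list(label_id = next_id, mask = m, area_px = area,
           bbox = c(row_min = rows[1], col_min = cols[1],
                    row_max = rows[2] + 1L, col_max = cols[2] + 1L)),
      class = "fd_nucleus_roi")
    next_id <- next_id + 1L
  }
  rois
}

#' Segment nuclei in the nuclear (DAPI) channel
#'
#' Pipeline: disk median filter, CLAHE, Otsu binarization, hole filling,
#' size filtering, then watershed splitting of touching components seeded
#' from distance-transform maxima.
#'
#' @param nuclear a [channel_image()] (role `"nuclear"`).
#' @param cfg a [segmentation_config()].
#' @return list of `fd_nucleus_roi` objects (label_id, full-frame logical
#'   mask, half-open bbox `(row_min, col_min, row_max, col_max)`, area_px).
#'   Pairwise disjoint; an empty or constant image yields an empty list.
#' @export
segment_nuclei <- function(nuclear, cfg = segmentation_config()) {
  if (!inherits(nuclear, "fd_channel_image"))
    fd_stop("nuclear must be an fd_channel_image", "fd_value_error")
  px <- nuclear$pixels
  if (max(px) <= min(px)) return(list())
  med <- cpp_rank_filter(quantize8(px), cfg$median_radius_px, "median",
                         0, 0, 0L)
  eq <- cpp_clahe(med, cfg$clahe_tile_px, cfg$clahe_clip)
  thr <- tryCatch(otsu_threshold(eq), fd_degenerate_error = function(e) NULL)
  if (is.null(thr)) return(list())
  mask <- eq > thr
  if (!any(mask)) return(list())
  mask <- .fill_holes(mask)
  # drop specks before the (costly) watershed
  lab0 <- cpp_label(mask, 8L)
  if (cfg$min_nucleus_area_px > 0) {
    areas <- tabulate(lab0[lab0 > 0])
    drop <- which(areas < cfg$min_nucleus_area_px)
    if (length(drop)) mask[lab0 %in% drop] <- FALSE
  }
  if (!any(mask)) return(list())
  dist <- cpp_edt(mask)
  # smooth the distance map so one nucleus yields one summit, not a plateau
  peaks <- cpp_peak_coords(gaussian_blur(dist, 2), cfg$peak_min_distance_px,
                           1e-3, mask)
  if (nrow(peaks) == 0) return(list())
  markers <- matrix(0L, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(peaks)))
    markers[peaks[i, 1] + 1L, peaks[i, 2] + 1L] <- i
  labels <- cpp_watershed(-dist, markers, mask)
  # merge watershed fragments below the area floor into nothing (rare)
  .roi_from_labels(labels, max(1L, cfg$min_nucleus_area_px), cfg$exclude_border)
}

#' Combine nucleus ROIs into one label mask
#'
#' @param rois list of `fd_nucleus_roi`.
#' @param dim image dimensions `c(rows, cols)`.
#' @return integer matrix, 0 = background, k = ROI `label_id`.
#' @export
roi_label_mask <- function(rois, dim) {
  lab <- matrix(0L, dim[1], dim[2])
  for (r in rois) lab[r$mask] <- r$label_id
  lab
}
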