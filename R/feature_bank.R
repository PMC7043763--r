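# The per-pixel feature space: a bank of sized neighborhood filters applied
# at multiple scales, plus Scharr edge magnitude, multi-scale Frangi
# vesselness, Gabor magnitude channels and the raw image.
#
# Rank/percentile/bilateral/entropy filters operate on an 8-bit quantized
# view of the normalized image over a disk footprint of the given radius;
# derivative-based filters operate on the real-valued image.  All channels
# are on a roughly [0,1] scale; exact standardization (z-scoring) happens
# once, inside the PCA fit, with statistics stored in the model.

.SIZED_FILTERS <- c("auto_level", "auto_level_percentile", "local_hist_eq",
                    "gradient", "gradient_percentile", "maximum", "minimum",
                    "mean", "mean_percentile", "bilateral_mean", "median",
                    "modal", "entropy", "tophat", "anisotropy")

.REMOVED_IN_REDUCED <- c("auto_level_percentile", "gradient_percentile",
                         "mean_percentile", "bilateral_mean", "median")

#' Filter bank configuration
#'
#' @param sized_filters character vector of sized neighborhood filters,
#'   subset of `auto_level, auto_level_percentile, local_hist_eq, gradient,
#'   gradient_percentile, maximum, minimum, mean, mean_percentile,
#'   bilateral_mean, median, modal, entropy, tophat, anisotropy`.
#' @param sizes_px strictly increasing filter sizes (disk radii, px).
#' @param gabor_frequencies strictly increasing spatial frequencies in
#'   (0, 0.5) cycles/px; one magnitude channel per frequency.
#' @param frangi_scale_start,frangi_scale_end,frangi_scale_step Frangi
#'   vesselness scale sweep; a start of 0 is replaced by one step (a
#'   zero-scale Hessian is undefined); one channel (max over scales).
#' @param include_scharr add the Scharr gradient-magnitude channel.
#' @param include_raw add the raw image as a channel.
#' @return an `fd_filter_bank_config` object.
#' @export
filter_bank_config <- function(sized_filters = .SIZED_FILTERS,
                               sizes_px = c(2L, 3L, 4L, 5L, 8L, 10L, 15L, 20L, 25L, 30L, 35L),
                               gabor_frequencies = c(0.08, 0.10, 0.13, 0.16, 0.2),
                               frangi_scale_start = 0,
                               frangi_scale_end = 5,
                               frangi_scale_step = 0.3,
                               include_scharr = TRUE,
                               include_raw = TRUE) {
  bad <- setdiff(sized_filters, .SIZED_FILTERS)
  if (length(bad))
    fd_stop(sprintf("unknown sized filters: %s", paste(bad, collapse = ", ")),
            "fd_value_error")
  if (length(sizes_px) && any(diff(sizes_px) <= 0))
    fd_stop("sizes_px must be strictly increasing", "fd_value_error")
  if (any(sizes_px < 1))
    fd_stop("sizes_px must be positive", "fd_value_error")
  if (length(gabor_frequencies) &&
      (any(diff(gabor_frequencies) <= 0) ||
       any(gabor_frequencies <= 0) || any(gabor_frequencies >= 0.5)))
    fd_stop("gabor_frequencies must be strictly increasing in (0, 0.5)",
            "fd_value_error")
  if (frangi_scale_end <= frangi_scale_start)
    fd_stop("frangi_scale_end must exceed frangi_scale_start", "fd_value_error")
  if (frangi_scale_step <= 0)
    fd_stop("frangi_scale_step must be positive", "fd_value_error")
  structure(list(sized_filters = sized_filters,
                 sizes_px = as.integer(sizes_px),
                 gabor_frequencies = gabor_frequencies,
                 frangi_scale_start = frangi_scale_start,
                 frangi_scale_end = frangi_scale_end,
                 frangi_scale_step = frangi_scale_step,
                 include_scharr = isTRUE(include_scharr),
                 include_raw = isTRUE(include_raw)),
            class = "fd_filter_bank_config")
}

#' Full 173-channel filter bank
#'
#' 15 sized filters at sizes 2,3,4,5,8,10,15,20,25,30,35 px (165 channels)
#' plus Scharr, Frangi (scales 0.3..4.8 by 0.3, one channel), 5 Gabor
#' frequencies (0.08, 0.10, 0.13, 0.16, 0.2) and the raw image.
#'
#' @return an `fd_filter_bank_config`.
#' @export
full_bank_config <- function() filter_bank_config()

#' Reduced 36-channel filter bank
#'
#' Drops the five near-redundant sized filters (auto-level percentile,
#' gradient percentile, mean percentile, bilateral mean, median), keeps one
#' small/medium/large size triple (2, 10, 30 px) and three Gabor
#' frequencies (0.08, 0.16, 0.2): 10 x 3 + Scharr + Frangi + 3 + raw = 36.
#'
#' @return an `fd_filter_bank_config`.
#' @export
reduced_bank_config <- function() {
  filter_bank_config(sized_filters = setdiff(.SIZED_FILTERS, .REMOVED_IN_REDUCED),
                     sizes_px = c(2L, 10L, 30L),
                     gabor_frequencies = c(0.08, 0.16, 0.2))
}

#' Channel names of a bank configuration
#' @param cfg an `fd_filter_bank_config`.
#' @return character vector, one name per channel, in application order.
#' @export
bank_channel_names <- function(cfg) {
  nm <- character(0)
  for (f in cfg$sized_filters)
    nm <- c(nm, sprintf("%s_s%d", f, cfg$sizes_px))
  if (cfg$include_scharr) nm <- c(nm, "scharr")
  nm <- c(nm, "frangi")
  nm <- c(nm, sprintf("gabor_f%.2f", cfg$gabor_frequencies))
  if (cfg$include_raw) nm <- c(nm, "raw")
  nm
}

#' Closed-form channel count of a bank configuration
#' @param cfg an `fd_filter_bank_config`.
#' @return integer channel count.
#' @export
n_bank_channels <- function(cfg) {
  length(cfg$sized_filters) * length(cfg$sizes_px) +
    length(cfg$gabor_frequencies) + cfg$include_scharr + 1L + cfg$include_raw
}

## ---- individual filters ---------------------------------------------------

.scharr_magnitude <- function(px) {
  kx <- matrix(c(-3, 0, 3, -10, 0, 10, -3, 0, 3), 3, byrow = TRUE) / 32
  gx <- cpp_convolve2(px, kx)
  gy <- cpp_convolve2(px, t(kx))
  sqrt(gx^2 + gy^2)
}

.gabor_magnitude <- function(px, frequency, bandwidth = 1) {
  # sigma from bandwidth as in standard Gabor parameterizations
  sigma <- (1 / pi) * sqrt(log(2) / 2) * (2^bandwidth + 1) / (2^bandwidth - 1) / frequency
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  xs <- -r:r
  env_y <- exp(-xs^2 / (2 * sigma^2))
  env_x <- exp(-xs^2 / (2 * sigma^2))
  # orientation 0: modulation along x; kernel separable for both parts
  re_x <- env_x * cos(2 * pi * frequency * xs)
  im_x <- env_x * sin(2 * pi * frequency * xs)
  norm <- 2 * pi * sigma^2
  re <- cpp_sepconv(px, env_y, re_x) / norm
  im <- cpp_sepconv(px, env_y, im_x) / norm
  sqrt(re^2 + im^2)
}

.hessian_eigen <- function(px, sigma) {
  b <- gaussian_blur(px, sigma)
  H <- nrow(b); W <- ncol(b)
  shift <- function(m, dy, dx) {
    ri <- pmin(pmax(seq_len(H) + dy, 1), H)
    ci <- pmin(pmax(seq_len(W) + dx, 1), W)
    m[ri, ci, drop = FALSE]
  }
  gxx <- shift(b, 0, 1) - 2 * b + shift(b, 0, -1)
  gyy <- shift(b, 1, 0) - 2 * b + shift(b, -1, 0)
  gxy <- (shift(b, 1, 1) - shift(b, 1, -1) - shift(b, -1, 1) + shift(b, -1, -1)) / 4
  s2 <- sigma^2  # gamma-normalized second derivatives
  gxx <- gxx * s2; gyy <- gyy * s2; gxy <- gxy * s2
  tmp <- sqrt(((gxx - gyy) / 2)^2 + gxy^2)
  mid <- (gxx + gyy) / 2
  list(l1 = mid + tmp, l2 = mid - tmp)  # l1 >= l2
}

.frangi <- function(px, scale_start, scale_end, scale_step,
                    beta = 0.5, c = 15 / 255) {
  scales <- seq(max(scale_start, scale_step), scale_end, by = scale_step)
  out <- matrix(0, nrow(px), ncol(px))
  for (s in scales) {
    ev <- .hessian_eigen(px, s)
    # order by |lambda|: |la| <= |lb|
    swap <- abs(ev$l1) > abs(ev$l2)
    la <- ifelse(swap, ev$l2, ev$l1)
    lb <- ifelse(swap, ev$l1, ev$l2)
    rb2 <- (la / ifelse(lb == 0, 1e-10, lb))^2
    s2 <- la^2 + lb^2
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * c^2)))
    v[lb > 0] <- 0  # bright (ridge-like) structures only
    out <- pmax(out, v)
  }
  out
}

#' Local structure-tensor anisotropy
#'
#' Per-pixel anisotropy score `1 - lambda2/lambda1` of the structure tensor
#' averaged over a disk of the given radius (`lambda1 >= lambda2 >= 0`;
#' defined as 0 where `lambda1` vanishes).  Rotation-symmetric blobs score
#' near 0; line-like structures near 1.
#'
#' @param foci a [channel_image()] or numeric matrix.
#' @param size_px disk radius in pixels, >= 2.
#' @return numeric matrix with values in [0,1].
#' @export
anisotropy_filter <- function(foci, size_px) {
  px <- if (inherits(foci, "fd_channel_image")) foci$pixels else foci
  if (!is.numeric(size_px) || length(size_px) != 1 || size_px < 2)
    fd_stop("size_px must be a single integer >= 2", "fd_value_error")
  sob <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE) / 8
  gx <- cpp_convolve2(px, sob)
  gy <- cpp_convolve2(px, t(sob))
  a <- cpp_disk_mean(gx * gx, as.integer(size_px))
  b <- cpp_disk_mean(gx * gy, as.integer(size_px))
  c_ <- cpp_disk_mean(gy * gy, as.integer(size_px))
  tmp <- sqrt(((a - c_) / 2)^2 + b^2)
  l1 <- (a + c_) / 2 + tmp
  l2 <- (a + c_) / 2 - tmp
  out <- ifelse(l1 > 1e-14, 1 - pmax(l2, 0) / l1, 0)
  matrix(pmin(pmax(out, 0), 1), nrow(px))
}

#' Apply one sized neighborhood filter
#'
#' Disk footprint of radius `size_px`.  Rank-type filters (and the
#' percentile, bilateral and entropy variants) act on an 8-bit quantized
#' view; `tophat` is the white top-hat (image minus its morphological
#' opening); `anisotropy` is [anisotropy_filter()].  Percentile windows:
#' auto-level (p20, p90), gradient (p10, p90), mean (p20, p80); the
#' bilateral mean admits neighbors within +-15 grey levels.
#'
#' @param px numeric matrix in [0,1].
#' @param name one of the sized filter names (see [filter_bank_config()]).
#' @param size_px disk radius in pixels.
#' @return numeric matrix; intensity-like outputs are on [0,1], entropy in
#'   bits.
#' @export
sized_filter <- function(px, name, size_px) {
  size_px <- as.integer(size_px)
  if (name == "anisotropy") return(anisotropy_filter(px, max(2L, size_px)))
  q <- quantize8(px)
  switch(name,
    auto_level = cpp_rank_filter(q, size_px, "auto_level", 0, 0, 0L),
    auto_level_percentile =
      cpp_rank_filter(q, size_px, "auto_level_percentile", 0.2, 0.9, 0L),
    local_hist_eq = cpp_rank_filter(q, size_px, "local_hist_eq", 0, 0, 0L),
    gradient = cpp_rank_filter(q, size_px, "gradient", 0, 0, 0L),
    gradient_percentile =
      cpp_rank_filter(q, size_px, "gradient_percentile", 0.1, 0.9, 0L),
    maximum = cpp_rank_filter(q, size_px, "maximum", 0, 0, 0L),
    minimum = cpp_rank_filter(q, size_px, "minimum", 0, 0, 0L),
    mean = cpp_rank_filter(q, size_px, "mean", 0, 0, 0L),
    mean_percentile =
      cpp_rank_filter(q, size_px, "mean_percentile", 0.2, 0.8, 0L),
    bilateral_mean =
      cpp_rank_filter(q, size_px, "bilateral_mean", 0, 0, 15L),
    median = cpp_rank_filter(q, size_px, "median", 0, 0, 0L),
    modal = cpp_rank_filter(q, size_px, "modal", 0, 0, 0L),
    entropy = cpp_rank_filter(q, size_px, "entropy", 0, 0, 0L) / 8,
    tophat = {
      er <- cpp_rank_filter(q, size_px, "minimum", 0, 0, 0L)
      op <- cpp_rank_filter(quantize8(er), size_px, "maximum", 0, 0, 0L)
      pmax(q / 255 - op, 0)
    },
    fd_stop(sprintf("unknown sized filter: %s", name), "fd_value_error")
  )
}

#' Compute the per-pixel feature stack for a foci image
#'
#' @param foci a [channel_image()] (role `"foci"`) or a numeric matrix in
#'   [0,1].
#' @param cfg an `fd_filter_bank_config`.
#' @return an `fd_feature_stack`: 3-D array `height x width x n_channels`
#'   with `channel_names` and `meta` attributes.
#' @export
apply_bank <- function(foci, cfg = full_bank_config()) {
  is_ci <- inherits(foci, "fd_channel_image")
  px <- if (is_ci) foci$pixels else foci
  meta <- if (is_ci) foci$meta else image_meta(ncol(px), nrow(px), 1)
  if (length(cfg$sizes_px) &&
      min(dim(px)) < 2 * max(cfg$sizes_px) + 1)
    fd_stop("image is smaller than the largest filter window", "fd_size_error")
  nm <- bank_channel_names(cfg)
  out <- array(0, dim = c(nrow(px), ncol(px), length(nm)))
  k <- 0L
  for (f in cfg$sized_filters)
    for (s in cfg$sizes_px) {
      k <- k + 1L
      out[, , k] <- sized_filter(px, f, s)
    }
  if (cfg$include_scharr) {
    k <- k + 1L
    out[, , k] <- .scharr_magnitude(px)
  }
  k <- k + 1L
  out[, , k] <- .frangi(px, cfg$frangi_scale_start, cfg$frangi_scale_end,
                        cfg$frangi_scale_step)
  for (fr in cfg$gabor_frequencies) {
    k <- k + 1L
    out[, , k] <- .gabor_magnitude(px, fr)
  }
  if (cfg$include_raw) {
    k <- k + 1L
    out[, , k] <- px
  }
  stopifnot(k == length(nm))
  structure(out, channel_names = nm, meta = meta,
            class = c("fd_feature_stack", class(out)))
}

#' Flatten a feature stack to a pixel-by-channel matrix
#' @param stack an `fd_feature_stack`.
#' @return numeric matrix `n_pixels x n_channels` (pixels in column-major
#'   image order), with channel names as column names.
#' @export
stack_to_matrix <- function(stack) {
  d <- dim(stack)
  m <- matrix(as.numeric(stack), d[1] * d[2], d[3])
  colnames(m) <- attr(stack, "channel_names")
  m
}
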