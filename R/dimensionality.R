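# PCA projection of the filter-bank feature space: components cumulatively
# explaining a target fraction (default 95%) of the variance of pooled
# training pixels are retained.

#' Fit a PCA projection on pooled training-pixel features
#'
#' Features are centered and (by default) z-scored before the
#' eigendecomposition; the stored projection folds both in, so applying it
#' at prediction time reproduces the training-time scaling exactly.
#' Constant (zero-variance) channels are dropped from the decomposition
#' with a warning; their component coefficients are zero.
#'
#' The number of retained components is the smallest k whose explained
#' variance ratios cumulatively reach `variance_threshold`.  Component
#' signs are fixed by making each component's largest-magnitude coefficient
#' positive.
#'
#' @param training_features numeric matrix `n_pixels x n_channels`,
#'   `n_pixels > n_channels`, all finite.
#' @param variance_threshold cumulative explained-variance target in (0,1].
#' @param scale. z-score channels before the fit (default TRUE; filters
#'   have incommensurate ranges and PCA is scale-sensitive).
#' @param max_pixels fit on at most this many uniformly subsampled rows
#'   (covariance estimates converge far below typical pixel counts).
#' @param seed seed for the row subsample.
#' @return an `fd_pca` object with fields `mean_vector`, `scale_vector`,
#'   `components` (n_kept x n_channels, orthonormal rows),
#'   `explained_variance_ratio`, `variance_threshold`, `channel_names`.
#' @export
fit_pca <- function(training_features, variance_threshold = 0.95,
                    scale. = TRUE, max_pixels = 200000L, seed = 1L) {
  x <- as.matrix(training_features)
  if (!is.numeric(x) || any(!is.finite(x)))
    fd_stop("features must be finite numeric", "fd_value_error")
  if (nrow(x) <= ncol(x))
    fd_stop("need more pixels than channels to fit a PCA", "fd_value_error")
  if (variance_threshold <= 0 || variance_threshold > 1)
    fd_stop("variance_threshold must lie in (0, 1]", "fd_value_error")
  if (nrow(x) > max_pixels) {
    idx <- with_seed(seed, sample.int(nrow(x), max_pixels))
    x <- x[idx, , drop = FALSE]
  }
  p <- ncol(x)
  ctr <- colMeans(x)
  sdv <- apply(x, 2, sd)
  keep <- sdv > 1e-12
  if (!all(keep))
    warning(sprintf("dropping %d constant feature channel(s) before PCA",
                    sum(!keep)))
  if (!any(keep))
    fd_stop("all feature channels are constant", "fd_value_error")
  scl <- rep(1, p)
  if (scale.) scl[keep] <- sdv[keep]
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  pc <- prcomp(xs, center = FALSE, scale. = FALSE)
  var_ratio <- pc$sdev^2 / sum(pc$sdev^2)
  n_kept <- which(cumsum(var_ratio) >= variance_threshold - 1e-12)[1]
  rot <- t(pc$rotation[, seq_len(n_kept), drop = FALSE])  # n_kept x p_keep
  # deterministic sign: largest-|coefficient| entry positive
  for (i in seq_len(n_kept)) {
    j <- which.max(abs(rot[i, ]))
    if (rot[i, j] < 0) rot[i, ] <- -rot[i, ]
  }
  comps <- matrix(0, n_kept, p)
  comps[, keep] <- rot
  cn <- colnames(training_features)
  structure(list(mean_vector = ctr,
                 scale_vector = scl,
                 components = comps,
                 explained_variance_ratio = var_ratio[seq_len(n_kept)],
                 variance_threshold = variance_threshold,
                 channel_names = cn),
            class = "fd_pca")
}

#' Project features through a fitted PCA
#'
#' The projection is affine: subtract the stored channel means, divide by
#' the stored channel scales, multiply by the component matrix.
#'
#' @param x an `fd_feature_stack` or a numeric matrix
#'   `n_pixels x n_channels`.
#' @param pca an `fd_pca` from [fit_pca()].
#' @return matching container with `n_kept` channels: a feature stack in,
#'   feature stack out; a matrix in, matrix out.
#' @export
pca_project <- function(x, pca) {
  if (!inherits(pca, "fd_pca")) fd_stop("pca must be an fd_pca", "fd_value_error")
  is_stack <- inherits(x, "fd_feature_stack")
  m <- if (is_stack) stack_to_matrix(x) else as.matrix(x)
  if (ncol(m) != length(pca$mean_vector))
    fd_stop(sprintf("feature count %d does not match PCA input size %d",
                    ncol(m), length(pca$mean_vector)), "fd_shape_error")
  z <- sweep(sweep(m, 2, pca$mean_vector), 2, pca$scale_vector, "/")
  proj <- z %*% t(pca$components)
  colnames(proj) <- sprintf("PC%d", seq_len(ncol(proj)))
  if (!is_stack) return(proj)
  d <- dim(x)
  out <- array(proj, dim = c(d[1], d[2], ncol(proj)))
  structure(out, channel_names = colnames(proj), meta = attr(x, "meta"),
            class = c("fd_feature_stack", class(out)))
}
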