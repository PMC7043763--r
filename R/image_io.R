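# Image, mask and report input/output plus pixel-size metadata and
# magnification rescaling.
#
# Supported image formats are PNG (via the png package) and uncompressed
# single-channel TIFF (own minimal codec, 8/16-bit, single- and multi-page,
# both byte orders on read).  Integer data are normalized to [0,1] by the
# dtype maximum on read.  Proprietary microscope containers are out of
# scope; convert to TIFF/PNG upstream.

#' Image metadata: dimensions and physical pixel size
#'
#' Pixels are assumed square.  The reference geometry is a 1388x1038 px
#' field covering 162.6x121.6 um at 63x (0.1172 um/px) or 103.2x77.2 um at
#' 40x (0.0744 um/px).
#'
#' @param width_px,height_px image dimensions in pixels.
#' @param pixel_size_um physical size of one pixel in micrometres.
#' @return an `fd_image_meta` object.
#' @export
image_meta <- function(width_px, height_px, pixel_size_um) {
  if (!is.numeric(width_px) || width_px < 1 || width_px != round(width_px))
    fd_stop("width_px must be a positive integer", "fd_value_error")
  if (!is.numeric(height_px) || height_px < 1 || height_px != round(height_px))
    fd_stop("height_px must be a positive integer", "fd_value_error")
  fd_assert_scalar_pos(pixel_size_um, "pixel_size_um")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_size_um = as.numeric(pixel_size_um)),
            class = "fd_image_meta")
}

#' Single-channel image with metadata
#'
#' @param pixels numeric matrix of finite, non-negative intensities
#'   (rows = image rows).
#' @param meta an [image_meta()] object, or `NULL` to build one from
#'   `pixel_size_um`.
#' @param pixel_size_um pixel size in um, used when `meta` is `NULL`.
#' @param channel_role `"nuclear"` (DAPI) or `"foci"` (gammaH2AX).
#' @return an `fd_channel_image` object.
#' @export
channel_image <- function(pixels, meta = NULL, pixel_size_um = NULL,
                          channel_role = c("foci", "nuclear")) {
  channel_role <- match.arg(channel_role)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    fd_stop("pixels must be a numeric matrix", "fd_value_error")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    fd_stop("intensities must be finite and non-negative", "fd_value_error")
  if (is.null(meta)) {
    fd_assert_scalar_pos(pixel_size_um, "pixel_size_um")
    meta <- image_meta(ncol(pixels), nrow(pixels), pixel_size_um)
  }
  if (!inherits(meta, "fd_image_meta"))
    fd_stop("meta must be an fd_image_meta", "fd_value_error")
  if (nrow(pixels) != meta$height_px || ncol(pixels) != meta$width_px)
    fd_stop("pixel grid dimensions do not match metadata", "fd_dimension_error")
  structure(list(pixels = pixels, meta = meta, channel_role = channel_role),
            class = "fd_channel_image")
}

#' Binary or labeled mask with metadata
#'
#' @param pixels logical matrix (TRUE = foci pixel) or non-negative integer
#'   matrix of object labels (0 = background).
#' @param meta an [image_meta()]; defaults to a unit pixel size.
#' @return an `fd_label_mask` object.
#' @export
label_mask <- function(pixels, meta = NULL) {
  if (!is.matrix(pixels))
    fd_stop("pixels must be a matrix", "fd_value_error")
  if (is.logical(pixels)) {
    if (anyNA(pixels)) fd_stop("mask contains NA", "fd_value_error")
  } else if (is.numeric(pixels)) {
    if (anyNA(pixels) || any(pixels < 0) || any(pixels != round(pixels)))
      fd_stop("label values must be non-negative integers", "fd_value_error")
  } else fd_stop("mask must be logical or integer", "fd_value_error")
  if (is.null(meta)) meta <- image_meta(ncol(pixels), nrow(pixels), 1)
  if (nrow(pixels) != meta$height_px || ncol(pixels) != meta$width_px)
    fd_stop("mask dimensions do not match metadata", "fd_dimension_error")
  structure(list(pixels = pixels, meta = meta), class = "fd_label_mask")
}

#' @export
print.fd_channel_image <- function(x, ...) {
  cat(sprintf("<fd_channel_image %s: %dx%d px, %.4f um/px, range [%.3f, %.3f]>\n",
              x$channel_role, x$meta$width_px, x$meta$height_px,
              x$meta$pixel_size_um, min(x$pixels), max(x$pixels)))
  invisible(x)
}

## ---- minimal uncompressed grayscale TIFF codec ----------------------------

.tiff_read_all <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) fd_stop("not a TIFF file (too short)", "fd_format_error")
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    fd_stop("not a TIFF file (bad byte-order mark)", "fd_format_error")
  rdint <- function(off, size, n = 1L)
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            signed = size >= 4L, endian = endian)
  if (rdint(2, 2) != 42L) fd_stop("not a TIFF file (bad magic)", "fd_format_error")
  ifd_off <- readBin(raw[5:8], "integer", size = 4, endian = endian)
  pages <- list()
  while (ifd_off > 0) {
    n_tags <- rdint(ifd_off, 2)
    tags <- list()
    for (i in seq_len(n_tags)) {
      toff <- ifd_off + 2 + (i - 1) * 12
      tag <- rdint(toff, 2)
      typ <- rdint(toff + 2, 2)
      cnt <- readBin(raw[(toff + 5):(toff + 8)], "integer", size = 4, endian = endian)
      size <- c(1, 1, 2, 4, 8)[typ]
      if (is.na(size)) size <- 4
      if (size * cnt <= 4) {
        vals <- rdint(toff + 8, size, cnt)
      } else {
        voff <- readBin(raw[(toff + 9):(toff + 12)], "integer", size = 4, endian = endian)
        vals <- rdint(voff, size, cnt)
      }
      tags[[as.character(tag)]] <- vals
    }
    gt <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    w <- gt(256); h <- gt(257)
    if (is.null(w) || is.null(h))
      fd_stop("TIFF lacks dimension tags", "fd_format_error")
    bits <- gt(258, 8L)[1]
    if (!bits %in% c(8L, 16L))
      fd_stop("only 8- and 16-bit TIFF supported", "fd_format_error")
    if (gt(259, 1L)[1] != 1L)
      fd_stop("only uncompressed TIFF supported", "fd_format_error")
    if (gt(277, 1L)[1] != 1L)
      fd_stop("multi-sample TIFF is ambiguous; supply single-channel images",
              "fd_format_error")
    offs <- gt(273); cnts <- gt(279)
    if (is.null(offs)) fd_stop("TIFF lacks strip offsets", "fd_format_error")
    if (is.null(cnts)) cnts <- rep(w * h * bits / 8 / length(offs), length(offs))
    bytes <- raw(0)
    for (i in seq_along(offs))
      bytes <- c(bytes, raw[(offs[i] + 1):(offs[i] + cnts[i])])
    vals <- readBin(bytes, "integer", n = w * h, size = bits / 8,
                    signed = FALSE, endian = endian)
    px <- matrix(vals / (2^bits - 1), nrow = h, ncol = w, byrow = TRUE)
    pages[[length(pages) + 1]] <- px
    ifd_pos <- ifd_off + 2 + n_tags * 12
    ifd_off <- readBin(raw[(ifd_pos + 1):(ifd_pos + 4)], "integer", size = 4,
                       endian = endian)
  }
  pages
}

.tiff_write <- function(pages, path, bits = 16L) {
  if (!bits %in% c(8L, 16L)) fd_stop("bits must be 8 or 16", "fd_value_error")
  con <- file(path, "wb")
  on.exit(close(con))
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  writeBin(charToRaw("II"), con); w2(42)
  # layout: header(8) | per page: pixel data then IFD
  offset <- 8L
  n <- length(pages)
  data_off <- integer(n); ifd_off <- integer(n)
  sizes <- integer(n)
  for (i in seq_len(n)) {
    sizes[i] <- nrow(pages[[i]]) * ncol(pages[[i]]) * bits / 8
    data_off[i] <- offset
    ifd_off[i] <- offset + sizes[i] + (sizes[i] %% 2L)  # word-align IFD
    offset <- ifd_off[i] + 2L + 9L * 12L + 4L
  }
  w4(ifd_off[1])
  for (i in seq_len(n)) {
    px <- pages[[i]]
    vals <- as.integer(round(pmax(0, pmin(1, px)) * (2^bits - 1)))
    vals <- as.integer(t(matrix(vals, nrow = nrow(px))))  # row-major order
    if (bits == 16L) {
      b <- as.raw(rbind(vals %% 256L, vals %/% 256L))  # little-endian pairs
      writeBin(b, con)
    } else {
      writeBin(as.raw(vals), con)
    }
    if (sizes[i] %% 2L) writeBin(as.raw(0), con)
    w2(9)  # number of tags
    tag <- function(id, typ, cnt, val) {
      w2(id); w2(typ); w4(cnt)
      if (typ == 3 && cnt == 1) { w2(val); w2(0) } else w4(val)
    }
    tag(256, 4, 1, ncol(px))          # width
    tag(257, 4, 1, nrow(px))          # height
    tag(258, 3, 1, bits)              # bits per sample
    tag(259, 3, 1, 1)                 # no compression
    tag(262, 3, 1, 1)                 # BlackIsZero
    tag(273, 4, 1, data_off[i])       # strip offset
    tag(277, 3, 1, 1)                 # samples per pixel
    tag(278, 4, 1, nrow(px))          # rows per strip
    tag(279, 4, 1, sizes[i])          # strip byte count
    w4(if (i < n) ifd_off[i + 1] else 0)
  }
  invisible(path)
}

## ---- generic gray image read/write ----------------------------------------

.read_gray_matrix <- function(path, page = 1L) {
  if (!file.exists(path))
    fd_stop(sprintf("file not found: %s", path), "fd_io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- tryCatch(png::readPNG(path),
                   error = function(e) fd_stop(
                     sprintf("cannot decode PNG %s: %s", path, conditionMessage(e)),
                     "fd_format_error"))
    if (length(dim(px)) == 3) {
      nch <- dim(px)[3]
      chans <- lapply(seq_len(nch), function(k) px[, , k])
      gray <- nch <= 2 || (identical(chans[[1]], chans[[2]]) &&
                           identical(chans[[1]], chans[[3]]))
      if (!gray)
        fd_stop(sprintf("%s is multi-channel; supply single-channel images", path),
                "fd_format_error")
      px <- chans[[1]]
    }
    px
  } else if (ext %in% c("tif", "tiff")) {
    pages <- .tiff_read_all(path)
    if (page > length(pages))
      fd_stop(sprintf("%s has %d page(s); page %d requested", path,
                      length(pages), page), "fd_format_error")
    pages[[page]]
  } else {
    fd_stop(sprintf("unsupported image format: .%s (use PNG or TIFF)", ext),
            "fd_format_error")
  }
}

#' Read one grayscale image to a [0,1] matrix
#'
#' @param path PNG or TIFF file path.
#' @param page page index for multi-page TIFF.
#' @return numeric matrix in [0,1].
#' @export
read_gray_image <- function(path, page = 1L) .read_gray_matrix(path, page)

#' Write a [0,1] matrix (or list of matrices) as a grayscale image
#'
#' PNG output uses the png package; TIFF output is uncompressed grayscale
#' (a list of matrices yields a multi-page TIFF).
#'
#' @param pixels numeric matrix in [0,1], or a list of such matrices (TIFF
#'   only).
#' @param path destination ending in .png, .tif or .tiff.
#' @param bits 8 or 16.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(pixels, path, bits = 16L) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (is.list(pixels)) fd_stop("PNG cannot hold multiple pages", "fd_value_error")
    png::writePNG(pmax(0, pmin(1, pixels)), path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!is.list(pixels)) pixels <- list(pixels)
    .tiff_write(pixels, path, bits = as.integer(bits))
  } else {
    fd_stop(sprintf("unsupported image format: .%s", ext), "fd_format_error")
  }
  invisible(path)
}

#' Read a registered nuclear/foci channel pair
#'
#' Both files must decode to single-channel grayscale images of identical
#' dimensions; 8/16-bit integer data are normalized to [0,1] by the dtype
#' maximum.  A two-page TIFF may be given as both paths (page 1 = nuclear,
#' page 2 = foci).
#'
#' @param nuclear_path,foci_path image files (PNG or TIFF).
#' @param pixel_size_um physical pixel size shared by both channels.
#' @return list with elements `nuclear` and `foci`, two [channel_image()]s
#'   sharing one metadata object.
#' @export
read_image_pair <- function(nuclear_path, foci_path, pixel_size_um) {
  fd_assert_scalar_pos(pixel_size_um, "pixel_size_um")
  two_page <- identical(normalizePath(nuclear_path, mustWork = FALSE),
                        normalizePath(foci_path, mustWork = FALSE))
  nuc <- .read_gray_matrix(nuclear_path, page = 1L)
  foc <- .read_gray_matrix(foci_path, page = if (two_page) 2L else 1L)
  if (!all(dim(nuc) == dim(foc)))
    fd_stop(sprintf("channel dimensions differ: %dx%d vs %dx%d",
                    nrow(nuc), ncol(nuc), nrow(foc), ncol(foc)),
            "fd_dimension_error")
  meta <- image_meta(ncol(nuc), nrow(nuc), pixel_size_um)
  list(nuclear = channel_image(nuc, meta, channel_role = "nuclear"),
       foci = channel_image(foc, meta, channel_role = "foci"))
}

#' Rescale an image to a target physical pixel size
#'
#' Bilinear interpolation; when downscaling, a Gaussian anti-alias
#' prefilter with sigma = (1/scale - 1)/2 is applied first.  Output
#' dimensions are `round(dim * pixel_size / target)`.  Test images taken at
#' a different magnification are rescaled this way to the training pixel
#' size before feature extraction.
#'
#' @param img a [channel_image()].
#' @param target_pixel_size_um desired um-per-pixel.
#' @return a [channel_image()] at the target pixel size.
#' @export
rescale_to_pixel_size <- function(img, target_pixel_size_um) {
  if (!inherits(img, "fd_channel_image"))
    fd_stop("img must be an fd_channel_image", "fd_value_error")
  fd_assert_scalar_pos(target_pixel_size_um, "target_pixel_size_um")
  s <- img$meta$pixel_size_um / target_pixel_size_um
  out_w <- max(1L, as.integer(round(img$meta$width_px * s)))
  out_h <- max(1L, as.integer(round(img$meta$height_px * s)))
  if (out_w == img$meta$width_px && out_h == img$meta$height_px &&
      isTRUE(all.equal(target_pixel_size_um, img$meta$pixel_size_um)))
    return(img)
  px <- img$pixels
  if (s < 1) px <- gaussian_blur(px, (1 / s - 1) / 2)
  px <- cpp_resize_bilinear(px, out_h, out_w)
  px <- pmax(px, 0)
  channel_image(px, image_meta(out_w, out_h, target_pixel_size_um),
                channel_role = img$channel_role)
}

#' Write a metrics table to CSV
#'
#' @param rows non-empty data frame of per-image/per-model metrics.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0)
    fd_stop("rows must be a non-empty data frame", "fd_value_error")
  ok <- tryCatch({ write.csv(rows, path, row.names = FALSE); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) fd_stop(sprintf("cannot write report to %s", path), "fd_io_error")
  invisible(path)
}

#' Read a metrics table written by [write_report()]
#' @param path CSV path.
#' @return data frame.
#' @export
read_report <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Write focus centers to JSON
#'
#' The on-disk convention is a list of `{x, y}` objects in 0-based pixel
#' coordinates with `x` = column; in R, centers are 1-based (row, col)
#' matrices.
#'
#' @param centers numeric matrix with columns `row`, `col` (1-based).
#' @param path destination JSON path.
#' @return `path`, invisibly.
#' @export
write_centers <- function(centers, path) {
  centers <- as.matrix(centers)
  df <- data.frame(x = centers[, 2] - 1, y = centers[, 1] - 1)
  jsonlite::write_json(df, path, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read focus centers from JSON
#' @param path JSON file of `{x, y}` objects (0-based, x = column).
#' @return numeric matrix with columns `row`, `col` (1-based).
#' @export
read_centers <- function(path) {
  df <- jsonlite::fromJSON(path)
  if (length(df) == 0 || nrow(as.data.frame(df)) == 0)
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  df <- as.data.frame(df)
  cbind(row = df$y + 1, col = df$x + 1)
}
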