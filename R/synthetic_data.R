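# Seeded synthetic two-channel scenes with ground truth, emulating the five
# image-quality regimes seen in real gammaH2AX data: good, noisy (high
# background / low SNR), labeling artefacts, halos around foci, and
# apoptotic nuclei with large overexposed foci-channel structures.
# Artefact and apoptotic structures are deliberately absent from the
# ground truth so classifiers must learn to reject them.

#' Scene generator configuration
#'
#' Defaults emulate the training-scale geometry: foci are circular
#' Gaussian spots of radius ~4 px (diameter ~8 px, so the 5 px matching
#' radius is ~0.6 diameters), counts per nucleus are Poisson, and nuclei
#' are smooth elliptical blobs.
#'
#' @param image_size_px `(height, width)` in pixels.
#' @param n_nuclei nuclei to place (non-overlapping; placement failure
#'   after bounded retries raises an error).
#' @param nucleus_radius_px mean nucleus radius (jittered +-15%).
#' @param foci_per_nucleus_mean Poisson mean of the per-nucleus focus
#'   count.
#' @param focus_radius_px mean focus radius (jittered +-25%); the
#'   ground-truth mask marks a disk of this radius per focus.
#' @param min_focus_separation_px minimum distance between planted focus
#'   centers of one nucleus (default 2.5 focus radii), keeping planted
#'   foci resolvable by the circular-Hough splitter; candidate positions
#'   violating it are redrawn (bounded retries, then dropped).
#' @param focus_peak_intensity peak amplitude of a focus above background.
#' @param psf_sigma_px Gaussian spot width (point-spread proxy).
#' @param background_level foci-channel background.
#' @param noise_sigma additive Gaussian read-noise sd.
#' @param photons_per_unit Poisson shot-noise scale (larger = less shot
#'   noise; 0 disables).
#' @param regime one of `good, noisy, artefacts, halos, apoptotic`.
#' @param pixel_size_um physical pixel size recorded in the metadata.
#' @param seed integer seed; scenes are bit-reproducible given the seed.
#' @return an `fd_scene_config`.
#' @export
scene_config <- function(image_size_px = c(256L, 256L),
                         n_nuclei = 6L,
                         nucleus_radius_px = 26,
                         foci_per_nucleus_mean = 8,
                         focus_radius_px = 4,
                         min_focus_separation_px = 2.5 * focus_radius_px,
                         focus_peak_intensity = 0.7,
                         psf_sigma_px = 1.8,
                         background_level = 0.06,
                         noise_sigma = 0.02,
                         photons_per_unit = 400,
                         regime = c("good", "noisy", "artefacts", "halos",
                                    "apoptotic"),
                         pixel_size_um = 0.1172,
                         seed = 1L) {
  regime <- match.arg(regime)
  if (length(image_size_px) != 2 || any(image_size_px < 32))
    fd_stop("image_size_px must be (height, width), both >= 32",
            "fd_value_error")
  fd_assert_scalar_pos(nucleus_radius_px, "nucleus_radius_px")
  fd_assert_scalar_pos(focus_radius_px, "focus_radius_px")
  if (foci_per_nucleus_mean < 0)
    fd_stop("foci_per_nucleus_mean must be >= 0", "fd_value_error")
  if (focus_peak_intensity <= 0 || focus_peak_intensity > 1)
    fd_stop("focus_peak_intensity must lie in (0, 1]", "fd_value_error")
  if (background_level < 0 || background_level >= 1)
    fd_stop("background_level must lie in [0, 1)", "fd_value_error")
  if (noise_sigma < 0) fd_stop("noise_sigma must be >= 0", "fd_value_error")
  structure(list(image_size_px = as.integer(image_size_px),
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radius_px = nucleus_radius_px,
                 foci_per_nucleus_mean = foci_per_nucleus_mean,
                 focus_radius_px = focus_radius_px,
                 min_focus_separation_px = min_focus_separation_px,
                 focus_peak_intensity = focus_peak_intensity,
                 psf_sigma_px = psf_sigma_px,
                 background_level = background_level,
                 noise_sigma = noise_sigma,
                 photons_per_unit = photons_per_unit,
                 regime = regime,
                 pixel_size_um = pixel_size_um,
                 seed = as.integer(seed)),
            class = "fd_scene_config")
}

# Poisson focus counts; exposed separately so the sampling distribution can
# be tested at scale without rendering images.
draw_focus_counts <- function(n_nuclei, mean, seed) {
  with_seed(seed, rpois(n_nuclei, mean))
}

.add_spot <- function(img, r, c, amp, sigma) {
  H <- nrow(img); W <- ncol(img)
  rad <- ceiling(4 * sigma)
  y0 <- max(1, floor(r - rad)); y1 <- min(H, ceiling(r + rad))
  x0 <- max(1, floor(c - rad)); x1 <- min(W, ceiling(c + rad))
  if (y0 > y1 || x0 > x1) return(img)
  rr <- y0:y1; cc <- x0:x1
  d2 <- outer((rr - r)^2, (cc - c)^2, "+")
  img[rr, cc] <- img[rr, cc] + amp * exp(-d2 / (2 * sigma^2))
  img
}

.add_ring <- function(img, r, c, radius, amp, width) {
  H <- nrow(img); W <- ncol(img)
  rad <- ceiling(radius + 3 * width)
  y0 <- max(1, floor(r - rad)); y1 <- min(H, ceiling(r + rad))
  x0 <- max(1, floor(c - rad)); x1 <- min(W, ceiling(c + rad))
  if (y0 > y1 || x0 > x1) return(img)
  rr <- y0:y1; cc <- x0:x1
  d <- sqrt(outer((rr - r)^2, (cc - c)^2, "+"))
  img[rr, cc] <- img[rr, cc] + amp * exp(-(d - radius)^2 / (2 * width^2))
  img
}

.fill_ellipse <- function(mask, r, c, a, b, theta) {
  H <- nrow(mask); W <- ncol(mask)
  rad <- ceiling(max(a, b))
  y0 <- max(1, floor(r - rad)); y1 <- min(H, ceiling(r + rad))
  x0 <- max(1, floor(c - rad)); x1 <- min(W, ceiling(c + rad))
  if (y0 > y1 || x0 > x1) return(mask)
  rr <- y0:y1; cc <- x0:x1
  dy <- outer(rr - r, rep(1, length(cc)))
  dx <- outer(rep(1, length(rr)), cc - c)
  u <- dy * cos(theta) + dx * sin(theta)
  v <- -dy * sin(theta) + dx * cos(theta)
  mask[rr, cc] <- mask[rr, cc] | ((u / a)^2 + (v / b)^2 <= 1)
  mask
}

#' Generate one synthetic two-channel scene with ground truth
#'
#' Nuclei are smooth elliptical blobs in the nuclear channel; foci are
#' Gaussian spots at Poisson-count positions inside nuclei in the foci
#' channel.  Regime modifiers: `noisy` raises background and noise and
#' dims foci; `halos` adds a dim annulus (radius 2x, intensity 0.3x)
#' around each focus; `artefacts` adds bright streaks and blobs not
#' recorded as truth; `apoptotic` gives one nucleus large saturated
#' foci-channel structures not recorded as truth.  Deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [scene_config()].
#' @return list with `nuclear` and `foci` ([channel_image()]s) and
#'   `truth`: `nucleus_label_mask` (integer matrix), `foci_mask` (logical),
#'   `foci_centers` (per-nucleus list of (row, col) matrices),
#'   `foci_count` (integer vector).
#' @export
generate_scene <- function(cfg = scene_config()) {
  with_seed(cfg$seed, {
    H <- cfg$image_size_px[1]; W <- cfg$image_size_px[2]
    reg <- cfg$regime
    bg <- cfg$background_level
    noise <- cfg$noise_sigma
    peak <- cfg$focus_peak_intensity
    if (reg == "noisy") {
      bg <- max(bg, 0.25)
      noise <- max(noise, 0.08)
      peak <- peak * 0.6
    }

    # nucleus placement: rejection sampling, bounded retries
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    margin <- cfg$nucleus_radius_px * 1.15 + 2
    for (i in seq_len(cfg$n_nuclei)) {
      placed <- FALSE
      for (try in seq_len(200)) {
        r <- runif(1, margin, H - margin)
        c <- runif(1, margin, W - margin)
        rad <- cfg$nucleus_radius_px * runif(1, 0.85, 1.15)
        if (nrow(centers) == 0 ||
            all(sqrt((centers[, 1] - r)^2 + (centers[, 2] - c)^2) >
                (radii + rad) * 1.05)) {
          centers <- rbind(centers, c(r, c))
          radii <- c(radii, rad)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        fd_stop("could not place all nuclei without overlap; reduce n_nuclei or nucleus_radius_px",
                "fd_placement_error")
    }
    n <- nrow(centers)

    nucleus_mask <- matrix(0L, H, W)
    nuclear <- matrix(0, H, W)
    ellipses <- vector("list", n)
    for (i in seq_len(n)) {
      a <- radii[i]
      b <- radii[i] * runif(1, 0.8, 1)
      th <- runif(1, 0, pi)
      ellipses[[i]] <- c(centers[i, ], a, b, th)
      m <- .fill_ellipse(matrix(FALSE, H, W), centers[i, 1], centers[i, 2],
                         a, b, th)
      nucleus_mask[m] <- i
      nuclear[m] <- nuclear[m] + runif(1, 0.5, 0.75)
    }
    nuclear <- gaussian_blur(nuclear, 2)

    # foci
    counts <- rpois(n, cfg$foci_per_nucleus_mean)
    foci <- matrix(bg, H, W)
    foci_mask <- matrix(FALSE, H, W)
    foci_centers <- vector("list", n)
    min_sep <- cfg$min_focus_separation_px
    for (i in seq_len(n)) {
      e <- ellipses[[i]]
      pts <- matrix(numeric(0), 0, 2)
      for (k in seq_len(counts[i])) {
        for (try in seq_len(100)) {
          # uniform inside the shrunken ellipse
          u <- sqrt(runif(1)); ang <- runif(1, 0, 2 * pi)
          uu <- 0.8 * e[3] * u * cos(ang)
          vv <- 0.8 * e[4] * u * sin(ang)
          r <- e[1] + uu * cos(e[5]) - vv * sin(e[5])
          c <- e[2] + uu * sin(e[5]) + vv * cos(e[5])
          if (nrow(pts) == 0 ||
              all(sqrt((pts[, 1] - r)^2 + (pts[, 2] - c)^2) >= min_sep)) {
            pts <- rbind(pts, c(r, c))
            break
          }
        }
      }
      counts[i] <- nrow(pts)  # drop foci that could not be separated
      foci_centers[[i]] <- pts
      for (k in seq_len(nrow(pts))) {
        amp <- peak * runif(1, 0.75, 1)
        frad <- cfg$focus_radius_px * runif(1, 0.75, 1.25)
        foci <- .add_spot(foci, pts[k, 1], pts[k, 2], amp, cfg$psf_sigma_px)
        foci_mask <- .fill_ellipse(foci_mask, pts[k, 1], pts[k, 2],
                                   frad, frad, 0)
        if (reg == "halos")
          foci <- .add_ring(foci, pts[k, 1], pts[k, 2],
                            2 * cfg$focus_radius_px, 0.3 * amp, 1.5)
      }
    }
    # labeled foci pixels never leave their nucleus
    foci_mask <- foci_mask & (nucleus_mask > 0)
    # faint nuclear autofluorescence in the foci channel
    foci <- foci + 0.05 * (nucleus_mask > 0)

    if (reg == "artefacts") {
      for (s in seq_len(3)) {
        r0 <- runif(1, 1, H); c0 <- runif(1, 1, W)
        th <- runif(1, 0, pi); len <- runif(1, 30, 80)
        for (t in seq(0, len, by = 0.5))
          foci <- .add_spot(foci, r0 + t * sin(th), c0 + t * cos(th),
                            0.5, 1.2)
      }
      for (s in seq_len(2))
        foci <- .add_spot(foci, runif(1, 1, H), runif(1, 1, W), 0.8, 6)
    }
    if (reg == "apoptotic" && n >= 1) {
      i <- sample.int(n, 1)
      for (s in seq_len(3)) {
        off <- runif(2, -0.4, 0.4) * radii[i]
        foci <- .add_spot(foci, centers[i, 1] + off[1],
                          centers[i, 2] + off[2], 1.5, radii[i] * 0.35)
      }
    }

    # noise: Poisson shot noise then Gaussian read noise
    if (cfg$photons_per_unit > 0) {
      foci <- matrix(rpois(H * W, pmax(foci, 0) * cfg$photons_per_unit) /
                       cfg$photons_per_unit, H, W)
      nuclear <- matrix(rpois(H * W, pmax(nuclear, 0) * cfg$photons_per_unit) /
                          cfg$photons_per_unit, H, W)
    }
    if (noise > 0) {
      foci <- foci + matrix(rnorm(H * W, 0, noise), H, W)
      nuclear <- nuclear + matrix(rnorm(H * W, 0, noise / 2), H, W)
    }
    foci <- pmin(pmax(foci, 0), 1)
    nuclear <- pmin(pmax(nuclear, 0), 1)

    meta <- image_meta(W, H, cfg$pixel_size_um)
    list(nuclear = channel_image(nuclear, meta, channel_role = "nuclear"),
         foci = channel_image(foci, meta, channel_role = "foci"),
         truth = list(nucleus_label_mask = nucleus_mask,
                      foci_mask = foci_mask,
                      foci_centers = foci_centers,
                      foci_count = counts))
  })
}

#' Generate a training set with a regime mixture
#'
#' Regime counts follow largest-remainder rounding of `n_images * mix`
#' (ties to the larger fraction); per-image seeds are derived
#' deterministically from the base config's seed.  The default mixture is
#' the observed nucleus-quality composition of the reference training set
#' (61.7% good, 24.4% noisy, 1.7% artefacts, 10.5% halos, 1.7% apoptotic).
#'
#' @param n_images number of scenes.
#' @param mix named numeric vector of regime fractions summing to 1.
#' @param cfg_base a [scene_config()] providing everything but the regime
#'   and the per-image seed.
#' @return list of [generate_scene()] results, with a `regimes` attribute.
#' @export
generate_training_set <- function(n_images,
                                  mix = c(good = 0.617, noisy = 0.244,
                                          artefacts = 0.017, halos = 0.105,
                                          apoptotic = 0.017),
                                  cfg_base = scene_config()) {
  if (n_images < 1) fd_stop("n_images must be >= 1", "fd_value_error")
  if (is.null(names(mix)) ||
      !all(names(mix) %in% c("good", "noisy", "artefacts", "halos",
                             "apoptotic")))
    fd_stop("mix must be named by regime", "fd_value_error")
  if (abs(sum(mix) - 1) > 1e-6)
    fd_stop("regime fractions must sum to 1", "fd_value_error")
  quota <- n_images * mix
  cnt <- floor(quota)
  rem <- quota - cnt
  leftover <- n_images - sum(cnt)
  if (leftover > 0) {
    ord <- order(rem, decreasing = TRUE)
    cnt[ord[seq_len(leftover)]] <- cnt[ord[seq_len(leftover)]] + 1
  }
  regimes <- rep(names(mix), cnt)
  # seeded interleave so regimes are not block-ordered (any train/test
  # split then sees a representative mixture)
  regimes <- with_seed(cfg_base$seed + 7L, sample(regimes))
  scenes <- lapply(seq_len(n_images), function(i) {
    cfg <- cfg_base
    cfg$regime <- regimes[i]
    cfg$seed <- cfg_base$seed + 1000L * i
    generate_scene(cfg)
  })
  attr(scenes, "regimes") <- regimes
  scenes
}
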