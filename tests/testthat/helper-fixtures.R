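# Shared fixtures and independent brute-force oracles.

# binary disk in an H x W frame
disk_mask <- function(H, W, r, c, radius) {
  d2 <- outer((seq_len(H) - r)^2, (seq_len(W) - c)^2, "+")
  d2 <= radius^2
}

# nuclear-channel-like scene: bright blurred disks on dark background
disk_scene <- function(H, W, centers, radius, value = 0.8) {
  px <- matrix(0, H, W)
  for (i in seq_len(nrow(centers)))
    px[disk_mask(H, W, centers[i, 1], centers[i, 2], radius)] <- value
  gaussian_blur(px, 1.5)
}

# proportion-separated 2-D Gaussian classes (all four base models,
# including complement NB, can separate these)
toy_gaussians <- function(n_per_class = 600, seed = 3) {
  set.seed(seed)
  X <- rbind(cbind(rnorm(n_per_class, 3, 0.5), rnorm(n_per_class, 1, 0.5)),
             cbind(rnorm(n_per_class, 1, 0.5), rnorm(n_per_class, 3, 0.5)))
  y <- rep(c(FALSE, TRUE), each = n_per_class)
  labeled_pixel_set(X, y)
}

# exhaustive Otsu: try every 8-bit bin boundary, maximize between-class
# variance computed by direct per-pixel partition
oracle_otsu_split <- function(px) {
  lo <- min(px); hi <- max(px)
  bin <- matrix(pmin(255L, as.integer((px - lo) / (hi - lo) * 256)), nrow(px))
  best_t <- NA; best_v <- -Inf
  for (t in 0:254) {
    g0 <- bin <= t; g1 <- !g0
    if (!any(g0) || !any(g1)) next
    w0 <- mean(g0); w1 <- mean(g1)
    v <- w0 * w1 * (mean(bin[g0]) - mean(bin[g1]))^2
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  bin > best_t  # foreground partition
}

# brute-force sliding-window maximum over a disk footprint
oracle_disk_max <- function(px, radius) {
  H <- nrow(px); W <- ncol(px)
  out <- matrix(0, H, W)
  for (y in seq_len(H))
    for (x in seq_len(W)) {
      vals <- c()
      for (dy in -radius:radius)
        for (dx in -radius:radius)
          if (dy * dy + dx * dx <= radius * radius) {
            yy <- min(max(y + dy, 1), H)  # close enough to mirror for interior checks
            xx <- min(max(x + dx, 1), W)
            vals <- c(vals, px[yy, xx])
          }
      out[y, x] <- max(vals)
    }
  out
}

# exhaustive maximum bipartite matching under a distance cap
oracle_max_matching <- function(auto, manual, radius) {
  na <- nrow(auto); nm <- nrow(manual)
  if (na == 0 || nm == 0) return(0L)
  d <- sqrt(outer(auto[, 1], manual[, 1], "-")^2 +
            outer(auto[, 2], manual[, 2], "-")^2)
  ok <- d <= radius
  best <- 0L
  recurse <- function(i, used) {
    if (i > na) return(0L)
    res <- recurse(i + 1, used)           # leave auto i unmatched
    for (j in seq_len(nm))
      if (ok[i, j] && !used[j]) {
        used[j] <- TRUE
        res <- max(res, 1L + recurse(i + 1, used))
        used[j] <- FALSE
      }
    res
  }
  recurse(1L, logical(nm))
}

# small, fast scene for pipeline-level tests
small_scene_cfg <- function(seed, regime = "good") {
  scene_config(image_size_px = c(128L, 128L), n_nuclei = 3L,
               nucleus_radius_px = 20, foci_per_nucleus_mean = 5,
               regime = regime, seed = seed)
}

# scaled-down segmentation settings for 128 px scenes
small_seg_cfg <- function() {
  segmentation_config(min_nucleus_area_px = 200L, peak_min_distance_px = 15,
                      clahe_tile_px = 64L)
}

table2_rows <- function() {
  m <- matrix(c(
    3475866, 3680, 154816, 172406,
    3621996, 36440, 122056, 26276,
    3532468, 46102, 112394, 115804,
    3625892, 37815, 120681, 22380,
    3622023, 37566, 120930, 26249,
    3625967, 37761, 120735, 22305,
    3577436, 46534, 111962, 70836,
    3630833, 42863, 115633, 17439,
    3633011, 59455, 99041, 15261,
    3634212, 60311, 98185, 14060,
    3620910, 33093, 125403, 27362,
    3564959, 26191, 132305, 83313,
    3567063, 24060, 134436, 81209,
    3624782, 38493, 120003, 23490,
    3625631, 38500, 119996, 22641), ncol = 4, byrow = TRUE)
  colnames(m) <- c("tn", "fn", "tp", "fp")
  rownames(m) <- c("SVM", "MLP", "cNB", "RF", "MLP+SVM", "RF+SVM", "cNB+SVM",
                   "MLP+RF", "cNB+MLP", "cNB+RF", "MLP+RF+SVM", "cNB+MLP+SVM",
                   "cNB+RF+SVM", "cNB+MLP+RF", "cNB+MLP+RF+SVM")
  m
}

table4_rows <- function() {
  m <- matrix(c(
    109, 2551, 372,
    497, 2163, 98,
    506, 2154, 91,
    130, 2530, 321,
    180, 2480, 253), ncol = 3, byrow = TRUE)
  colnames(m) <- c("fn", "tp", "fp")
  rownames(m) <- c("MLP", "RF", "MLP+RF", "MLP+RF+SVM", "cNB+MLP+RF+SVM")
  m
}

# printed object-wise metrics (sensitivity, ppv, fnr, f1) per model
table3_rows <- function() {
  m <- matrix(c(
    0.959, 0.873, 0.041, 0.914,
    0.813, 0.957, 0.187, 0.879,
    0.810, 0.959, 0.190, 0.878,
    0.951, 0.887, 0.049, 0.918,
    0.932, 0.907, 0.068, 0.920), ncol = 4, byrow = TRUE)
  colnames(m) <- c("sensitivity", "ppv", "fnr", "f1")
  rownames(m) <- rownames(table4_rows())
  m
}
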