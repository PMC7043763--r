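# End-to-end drivers: assemble labeled pixel sets from images + manual
# masks, train models, apply them to scenes and score the detections.

#' Build a labeled pixel set from foci images and manual masks
#'
#' Applies the filter bank to every image, optionally restricts pixels to
#' nucleus regions, subsamples pixels uniformly per image (keeping the raw
#' class imbalance), fits the z-scoring + PCA reduction on the pooled
#' sample and returns the projected features with labels, ready for
#' [train_pixel_model()].
#'
#' @param foci_images list of [channel_image()]s (foci channel).
#' @param truth_masks list of logical matrices (TRUE = focus pixel).
#' @param nucleus_masks optional list of logical/integer matrices
#'   restricting training pixels to nuclei (as manual labeling does).
#' @param bank_cfg an `fd_filter_bank_config`.
#' @param variance_threshold cumulative explained variance kept by the
#'   PCA.
#' @param pixels_per_image uniform random pixel subsample per image.
#' @param seed seed for subsampling and the PCA fit.
#' @return an [labeled_pixel_set()] carrying the fitted PCA and the bank
#'   config.
#' @export
build_training_set <- function(foci_images, truth_masks, nucleus_masks = NULL,
                               bank_cfg = reduced_bank_config(),
                               variance_threshold = 0.95,
                               pixels_per_image = 20000L, seed = 1L) {
  if (length(foci_images) != length(truth_masks))
    fd_stop("images and masks differ in length", "fd_shape_error")
  feats <- list(); labs <- list()
  for (i in seq_along(foci_images)) {
    img <- foci_images[[i]]
    stk <- apply_bank(img, bank_cfg)
    m <- stack_to_matrix(stk)
    y <- as.logical(truth_masks[[i]])
    keep <- rep(TRUE, nrow(m))
    if (!is.null(nucleus_masks))
      keep <- as.vector(nucleus_masks[[i]] > 0)
    idx <- which(keep)
    if (length(idx) > pixels_per_image)
      idx <- with_seed(seed + i, sort(sample(idx, pixels_per_image)))
    feats[[i]] <- m[idx, , drop = FALSE]
    labs[[i]] <- y[idx]
  }
  X <- do.call(rbind, feats)
  y <- unlist(labs)
  pca <- fit_pca(X, variance_threshold, seed = seed)
  labeled_pixel_set(pca_project(X, pca), y, pca = pca, bank_config = bank_cfg)
}

#' Detect and count foci in a two-channel image
#'
#' Full inference pass: segment nuclei in the nuclear channel, classify
#' foci pixels with the trained model (restricted to nuclei), size-filter,
#' split overlaps by circular Hough and report centers and per-nucleus
#' counts.
#'
#' @param model a trained `fd_foci_model`.
#' @param nuclear,foci [channel_image()]s of the two channels.
#' @param seg_cfg a [segmentation_config()].
#' @param post_cfg a [postprocess_config()].
#' @param models,rule voting members / rule overrides (see
#'   [predict_mask()]).
#' @return list with `rois`, `mask` (post size filter), `fociset`,
#'   `counts` (data frame nucleus / n_foci).
#' @export
count_foci <- function(model, nuclear, foci,
                       seg_cfg = segmentation_config(),
                       post_cfg = postprocess_config(),
                       models = NULL, rule = NULL) {
  rois <- segment_nuclei(nuclear, seg_cfg)
  pred <- predict_mask(model, foci, models = models, rule = rule)
  if (length(rois)) {
    roi_union <- Reduce(`|`, lapply(rois, `[[`, "mask"))
    px <- pred$pixels & roi_union
  } else px <- pred$pixels & FALSE
  filtered <- size_filter(label_mask(px, pred$meta), post_cfg$min_object_area_px)
  fociset <- detect_centers(filtered, foci, post_cfg)
  list(rois = rois, mask = filtered, fociset = fociset,
       counts = count_foci_per_nucleus(fociset, rois))
}

#' Score detected centers against ground truth, per nucleus and pooled
#'
#' Auto and manual centers are assigned to nuclei via the truth nucleus
#' label mask; centers falling outside any nucleus are pooled into a
#' pseudo-nucleus.  Matching within each nucleus uses
#' [match_centers()].
#'
#' @param auto_centers numeric matrix (row, col) of detected centers.
#' @param truth ground truth from [generate_scene()].
#' @param radius_px matching radius (default 5).
#' @return list with `per_nucleus` (list of `fd_tally`) and `pooled`
#'   (`fd_tally`).
#' @export
score_centers <- function(auto_centers, truth, radius_px = 5) {
  lab <- truth$nucleus_label_mask
  n <- max(lab, length(truth$foci_centers))
  assign_to <- function(centers) {
    if (length(centers) == 0 || nrow(centers) == 0) return(integer(0))
    ri <- pmin(pmax(round(centers[, 1]), 1), nrow(lab))
    ci <- pmin(pmax(round(centers[, 2]), 1), ncol(lab))
    lab[cbind(ri, ci)]
  }
  auto_centers <- matrix(as.numeric(auto_centers), ncol = 2)
  auto_n <- assign_to(auto_centers)
  tallies <- vector("list", n + 1)
  for (i in seq_len(n)) {
    manual <- truth$foci_centers[[i]]
    if (is.null(manual)) manual <- matrix(numeric(0), 0, 2)
    tallies[[i]] <- match_centers(auto_centers[auto_n == i, , drop = FALSE],
                                  manual, radius_px)
  }
  # detections outside every nucleus are pure false positives
  tallies[[n + 1]] <- detection_tally(tp = 0, fp = sum(auto_n == 0), fn = 0)
  pooled <- .pool_tallies(tallies)
  list(per_nucleus = tallies[seq_len(n)], pooled = pooled)
}

#' End-to-end synthetic recovery benchmark
#'
#' Generates `n_scenes` seeded scenes at the reference regime mixture,
#' trains an MLP pixel classifier on all but the last scene (reduced
#' filter bank, 95% PCA), runs full inference on the held-out scene and
#' scores the detected centers against the planted ground truth at the
#' given matching radius.
#'
#' @param seed base seed for scene generation, subsampling and training.
#' @param n_scenes total scenes (training uses `n_scenes - 1`).
#' @param scene_cfg base [scene_config()] (its seed is overridden).
#' @param pixels_per_image training-pixel subsample per scene.
#' @param match_radius_px center-matching radius.
#' @return list with `object_metrics` (an `fd_metric_report`),
#'   `pixel_metrics` (pixel-wise report on the held-out scene),
#'   `per_nucleus` tallies, the held-out `regime`, and `n_manual_foci`.
#' @export
synthetic_benchmark <- function(seed, n_scenes = 9L,
                                scene_cfg = scene_config(),
                                pixels_per_image = 12000L,
                                match_radius_px = 5) {
  scene_cfg$seed <- as.integer(seed)
  scenes <- generate_training_set(n_scenes, cfg_base = scene_cfg)
  train <- scenes[seq_len(n_scenes - 1)]
  test <- scenes[[n_scenes]]
  ts <- build_training_set(lapply(train, `[[`, "foci"),
                           lapply(train, function(s) s$truth$foci_mask),
                           nucleus_masks = lapply(train, function(s)
                             s$truth$nucleus_label_mask),
                           bank_cfg = reduced_bank_config(),
                           pixels_per_image = pixels_per_image,
                           seed = seed + 1L)
  mod <- train_pixel_model(classifier_spec("MLP", seed = seed + 2L), ts)
  res <- count_foci(mod, test$nuclear, test$foci)
  sc <- score_centers(res$fociset$centers, test$truth, match_radius_px)
  pm <- predict_mask(mod, test$foci)
  inside <- test$truth$nucleus_label_mask > 0
  pt <- pixel_tally(pm$pixels & inside, test$truth$foci_mask)
  list(object_metrics = compute_metrics(sc$pooled),
       pixel_metrics = compute_metrics(pt),
       per_nucleus = sc$per_nucleus,
       regime = attr(scenes, "regimes")[n_scenes],
       n_manual_foci = sum(test$truth$foci_count),
       model = mod)
}
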