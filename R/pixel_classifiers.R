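# Pixel classifiers and their ensemble combinations.
#
# Base learners follow the reference composition: a plain multi-layer
# perceptron; a linear SVM wrapped as bagging(10) over AdaBoost(15);
# AdaBoost(15) over complement naive Bayes and over a random forest.  Any
# non-empty subset of the four can be combined by a soft (mean
# probability) or hard (strict majority, ties negative) vote.

#' Classifier specification
#'
#' @param base_models non-empty subset of `c("MLP", "SVM", "cNB", "RF")`.
#' @param adaboost_estimators boosting rounds for SVM/RF/cNB (the MLP is
#'   never boosted).
#' @param bagging_estimators bagging members for the SVM.
#' @param voting_rule `"soft"` (mean probability > 0.5) or `"hard"`
#'   (strict majority of member labels; ties are negative).
#' @param seed integer seed controlling every stochastic element of
#'   training.
#' @param mlp_hidden,mlp_max_epochs MLP architecture/budget: one hidden
#'   ReLU layer of `mlp_hidden` units trained with Adam, stopping early
#'   when the loss plateaus.
#' @param rf_trees trees per random forest.
#' @return an `fd_classifier_spec`.
#' @export
classifier_spec <- function(base_models = c("MLP", "SVM", "cNB", "RF"),
                            adaboost_estimators = 15L,
                            bagging_estimators = 10L,
                            voting_rule = c("soft", "hard"),
                            seed = 1L,
                            mlp_hidden = 100L,
                            mlp_max_epochs = 200L,
                            rf_trees = 100L) {
  voting_rule <- match.arg(voting_rule)
  bad <- setdiff(base_models, c("MLP", "SVM", "cNB", "RF"))
  if (length(bad) || length(base_models) == 0)
    fd_stop("base_models must be a non-empty subset of MLP, SVM, cNB, RF",
            "fd_value_error")
  fd_assert_scalar_pos(adaboost_estimators, "adaboost_estimators")
  fd_assert_scalar_pos(bagging_estimators, "bagging_estimators")
  structure(list(base_models = unique(base_models),
                 adaboost_estimators = as.integer(adaboost_estimators),
                 bagging_estimators = as.integer(bagging_estimators),
                 voting_rule = voting_rule,
                 seed = as.integer(seed),
                 mlp_hidden = as.integer(mlp_hidden),
                 mlp_max_epochs = as.integer(mlp_max_epochs),
                 rf_trees = as.integer(rf_trees)),
            class = "fd_classifier_spec")
}

#' Labeled pixel features for training
#'
#' @param features numeric matrix `n_pixels x n_kept` (typically
#'   PCA-projected filter-bank features).
#' @param labels logical vector, TRUE = focus pixel.
#' @param pca,bank_config optional preprocessing objects carried along so
#'   the trained model can be applied to raw images.
#' @return an `fd_labeled_pixel_set`.
#' @export
labeled_pixel_set <- function(features, labels, pca = NULL, bank_config = NULL) {
  features <- as.matrix(features)
  labels <- as.logical(labels)
  if (nrow(features) != length(labels))
    fd_stop("features and labels lengths differ", "fd_shape_error")
  structure(list(features = features, labels = labels,
                 pca = pca, bank_config = bank_config),
            class = "fd_labeled_pixel_set")
}

## ---- multi-layer perceptron ----------------------------------------------

.fit_mlp <- function(X, y, hidden = 100L, max_epochs = 200L, batch = 200L,
                     lr = 1e-3, l2 = 1e-4, tol = 1e-4, patience = 10L,
                     seed = 1L) {
  n <- nrow(X); p <- ncol(X)
  with_seed(seed, {
    W1 <- matrix(rnorm(p * hidden, sd = sqrt(2 / p)), p, hidden)
    b1 <- rep(0, hidden)
    W2 <- matrix(rnorm(hidden, sd = sqrt(2 / hidden)), hidden, 1)
    b2 <- 0
    mW1 <- vW1 <- W1 * 0; mb1 <- vb1 <- b1 * 0
    mW2 <- vW2 <- W2 * 0; mb2 <- vb2 <- 0
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t <- 0
    yv <- as.numeric(y)
    best <- Inf; stale <- 0L
    batch <- min(batch, n)
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      loss_sum <- 0
      for (start in seq(1, n, by = batch)) {
        idx <- ord[start:min(start + batch - 1, n)]
        xb <- X[idx, , drop = FALSE]; yb <- yv[idx]
        A <- sweep(xb %*% W1, 2, b1, "+")
        Hh <- pmax(A, 0)
        z <- drop(Hh %*% W2) + b2
        pr <- plogis(z)
        m <- length(idx)
        loss_sum <- loss_sum - sum(log(ifelse(yb == 1, pr, 1 - pr) + 1e-12))
        dz <- (pr - yb) / m
        gW2 <- crossprod(Hh, dz) + l2 * W2
        gb2 <- sum(dz)
        dH <- (dz %*% t(W2)) * (A > 0)
        gW1 <- crossprod(xb, dH) + l2 * W1
        gb1 <- colSums(dH)
        t <- t + 1
        up <- function(m., v., g) {
          m. <- beta1 * m. + (1 - beta1) * g
          v. <- beta2 * v. + (1 - beta2) * g^2
          list(m = m., v = v.,
               d = lr * (m. / (1 - beta1^t)) / (sqrt(v. / (1 - beta2^t)) + eps))
        }
        u <- up(mW1, vW1, gW1); mW1 <- u$m; vW1 <- u$v; W1 <- W1 - u$d
        u <- up(mb1, vb1, gb1); mb1 <- u$m; vb1 <- u$v; b1 <- b1 - u$d
        u <- up(mW2, vW2, gW2); mW2 <- u$m; vW2 <- u$v; W2 <- W2 - u$d
        u <- up(mb2, vb2, gb2); mb2 <- u$m; vb2 <- u$v; b2 <- b2 - u$d
      }
      loss <- loss_sum / n
      if (loss > best - tol) stale <- stale + 1L else stale <- 0L
      if (loss < best) best <- loss
      if (stale >= patience) break
    }
    list(kind = "mlp", W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  })
}

.predict_mlp <- function(fit, X) {
  Hh <- pmax(sweep(X %*% fit$W1, 2, fit$b1, "+"), 0)
  drop(plogis(drop(Hh %*% fit$W2) + fit$b2))
}

## ---- linear SVM (squared hinge) with Platt scaling ------------------------

.fit_linsvm <- function(X, y, w = NULL, iters = 300L, lr = 0.05, l2 = 1e-3) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(w)) w <- rep(1, n)
  w <- w / sum(w)
  ys <- ifelse(y, 1, -1)
  beta <- rep(0, p); b0 <- 0
  mb <- vb <- rep(0, p); m0 <- v0 <- 0
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  for (t in seq_len(iters)) {
    f <- drop(X %*% beta) + b0
    slack <- pmax(0, 1 - ys * f)
    coefv <- -2 * slack * ys * w
    g <- drop(crossprod(X, coefv)) + 2 * l2 * beta
    g0 <- sum(coefv)
    mb <- beta1 * mb + (1 - beta1) * g
    vb <- beta2 * vb + (1 - beta2) * g^2
    beta <- beta - lr * (mb / (1 - beta1^t)) / (sqrt(vb / (1 - beta2^t)) + eps)
    m0 <- beta1 * m0 + (1 - beta1) * g0
    v0 <- beta2 * v0 + (1 - beta2) * g0^2
    b0 <- b0 - lr * (m0 / (1 - beta1^t)) / (sqrt(v0 / (1 - beta2^t)) + eps)
  }
  f <- drop(X %*% beta) + b0
  # Platt calibration of decision values to probabilities
  pl <- suppressWarnings(glm(y ~ f, family = binomial()))
  co <- coef(pl)
  if (anyNA(co)) co <- c(0, 4)
  list(kind = "linsvm", beta = beta, b0 = b0, platt = unname(co))
}

.predict_linsvm <- function(fit, X) {
  f <- drop(X %*% fit$beta) + fit$b0
  plogis(fit$platt[1] + fit$platt[2] * f)
}

## ---- complement naive Bayes ----------------------------------------------

# Complement NB is count-oriented and undefined for negative inputs, so it
# consumes min-max rescaled features; the scaler is stored with the fit.
.fit_cnb <- function(X, y, w = NULL, alpha = 1) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(w)) w <- rep(1, n)
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  rng <- ifelse(hi > lo, hi - lo, 1)
  Xs <- sweep(sweep(X, 2, lo), 2, rng, "/")
  flp <- matrix(0, 2, p)  # rows: class FALSE, TRUE
  for (ci in 1:2) {
    in_c <- if (ci == 2) y else !y
    comp <- colSums(Xs[!in_c, , drop = FALSE] * w[!in_c]) + alpha
    theta <- comp / sum(comp)
    flp[ci, ] <- -log(theta)
  }
  list(kind = "cnb", lo = lo, rng = rng, flp = flp)
}

.predict_cnb <- function(fit, X) {
  Xs <- sweep(sweep(X, 2, fit$lo), 2, fit$rng, "/")
  Xs <- pmin(pmax(Xs, 0), 1)
  jll <- Xs %*% t(fit$flp)
  m <- pmax(jll[, 1], jll[, 2])
  e <- exp(jll - m)
  drop(e[, 2] / (e[, 1] + e[, 2]))
}

## ---- random forest (C++ CART) ---------------------------------------------

.fit_rf <- function(X, y, w = NULL, n_tree = 100L, seed = 1L) {
  n <- nrow(X)
  if (is.null(w)) w <- rep(1, n)
  mtry <- max(1L, as.integer(floor(sqrt(ncol(X)))))
  trees <- cpp_rf_fit(X, as.integer(y), w, n_tree, mtry,
                      20L, 2L, as.integer(seed))
  list(kind = "rf", trees = trees)
}

.predict_rf <- function(fit, X) cpp_rf_predict(fit$trees, X)

## ---- AdaBoost (SAMME) and bagging wrappers --------------------------------

.fit_adaboost <- function(fitter, predictor, X, y, n_est, seed) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  members <- list(); alphas <- numeric(0)
  for (m in seq_len(n_est)) {
    fit <- fitter(X, y, w, seed + m)
    pred <- predictor(fit, X) > 0.5
    err <- sum(w[pred != y])
    if (err <= 1e-12) {
      members[[length(members) + 1]] <- fit
      alphas <- c(alphas, 10)
      break
    }
    if (err >= 0.5) {
      if (length(members) == 0) {
        members[[1]] <- fit
        alphas <- 1e-3
      }
      break
    }
    alpha <- log((1 - err) / err)
    members[[length(members) + 1]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
  }
  list(kind = "adaboost", members = members, alphas = alphas)
}

.predict_adaboost <- function(fit, X, base_predictor) {
  num <- rep(0, nrow(X)); den <- sum(fit$alphas)
  for (i in seq_along(fit$members)) {
    pred <- base_predictor(fit$members[[i]], X) > 0.5
    num <- num + fit$alphas[i] * pred
  }
  if (den <= 0) return(rep(0.5, nrow(X)))
  num / den
}

.fit_bagging <- function(fitter, X, y, n_est, seed) {
  n <- nrow(X)
  members <- with_seed(seed, {
    lapply(seq_len(n_est), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) < 2)  # ensure both classes in the resample
        idx <- c(idx, which(y != y[idx[1]])[1])
      fitter(X[idx, , drop = FALSE], y[idx], seed + 1000L * b)
    })
  })
  list(kind = "bagging", members = members)
}

.predict_bagging <- function(fit, X, member_predictor) {
  pr <- rep(0, nrow(X))
  for (m in fit$members) pr <- pr + member_predictor(m, X)
  pr / length(fit$members)
}

## ---- base-model dispatch --------------------------------------------------

.fit_base_model <- function(name, spec, X, y) {
  seed <- spec$seed
  switch(name,
    MLP = .fit_mlp(X, y, hidden = spec$mlp_hidden,
                   max_epochs = spec$mlp_max_epochs, seed = seed + 11L),
    RF = .fit_adaboost(
      function(X, y, w, s) .fit_rf(X, y, w, n_tree = spec$rf_trees, seed = s),
      .predict_rf, X, y, spec$adaboost_estimators, seed + 23L),
    cNB = .fit_adaboost(
      function(X, y, w, s) .fit_cnb(X, y, w),
      .predict_cnb, X, y, spec$adaboost_estimators, seed + 31L),
    SVM = .fit_bagging(
      function(Xb, yb, s) .fit_adaboost(
        function(X2, y2, w, s2) .fit_linsvm(X2, y2, w),
        .predict_linsvm, Xb, yb, spec$adaboost_estimators, s),
      X, y, spec$bagging_estimators, seed + 47L),
    fd_stop(sprintf("unknown base model %s", name), "fd_value_error"))
}

.predict_base_model <- function(name, fit, X) {
  switch(name,
    MLP = .predict_mlp(fit, X),
    RF = .predict_adaboost(fit, X, .predict_rf),
    cNB = .predict_adaboost(fit, X, .predict_cnb),
    SVM = .predict_bagging(fit, X, function(m, X2)
      .predict_adaboost(m, X2, .predict_linsvm)),
    fd_stop(sprintf("unknown base model %s", name), "fd_value_error"))
}

## ---- training and prediction ----------------------------------------------

#' Train pixel classifiers
#'
#' Fits every base model named in the spec on the labeled pixel set.  One
#' training pass yields components from which any voting combination of
#' the fitted members can be formed (see [predict_mask()]'s `models`
#' argument).
#'
#' @param spec a [classifier_spec()].
#' @param data an [labeled_pixel_set()]; both classes must be present.
#' @return an `fd_foci_model` carrying the fitted components plus the
#'   preprocessing (PCA, bank config) found on `data`.
#' @export
train_pixel_model <- function(spec, data) {
  if (!inherits(spec, "fd_classifier_spec"))
    fd_stop("spec must be an fd_classifier_spec", "fd_value_error")
  if (!inherits(data, "fd_labeled_pixel_set"))
    fd_stop("data must be an fd_labeled_pixel_set", "fd_value_error")
  X <- data$features; y <- data$labels
  if (any(!is.finite(X)))
    fd_stop("features must be finite", "fd_value_error")
  if (length(unique(y)) < 2)
    fd_stop("training data must contain both classes", "fd_training_error")
  comps <- list()
  for (nm in spec$base_models)
    comps[[nm]] <- .fit_base_model(nm, spec, X, y)
  structure(list(spec = spec, components = comps, pca = data$pca,
                 bank_config = data$bank_config,
                 training_pixel_count = nrow(X)),
            class = "fd_foci_model")
}

#' Per-model positive-class probabilities for projected features
#'
#' @param model an `fd_foci_model`.
#' @param features numeric matrix `n x n_kept` of projected features.
#' @param models which fitted members to evaluate (default: all).
#' @return numeric matrix `n x length(models)`, one probability column per
#'   model.
#' @export
predict_pixel_prob <- function(model, features, models = NULL) {
  if (is.null(models)) models <- names(model$components)
  missing <- setdiff(models, names(model$components))
  if (length(missing))
    fd_stop(sprintf("model has no fitted component(s): %s",
                    paste(missing, collapse = ", ")), "fd_value_error")
  out <- vapply(models, function(nm)
    .predict_base_model(nm, model$components[[nm]], features),
    numeric(nrow(features)))
  matrix(out, nrow = nrow(features),
         dimnames = list(NULL, models))
}

#' Combine member predictions by voting
#'
#' Soft voting averages probabilities and calls a pixel positive when the
#' mean exceeds 0.5; hard voting thresholds each member at 0.5 and
#' requires a strict majority (ties are negative).  A unanimous prediction
#' is never overturned by either rule.
#'
#' @param predictions list (or matrix columns) of per-model probability or
#'   label vectors of equal length.
#' @param rule `"soft"` or `"hard"`.
#' @return logical vector.
#' @export
vote <- function(predictions, rule = c("soft", "hard")) {
  rule <- match.arg(rule)
  if (is.matrix(predictions))
    predictions <- lapply(seq_len(ncol(predictions)), function(j) predictions[, j])
  if (length(predictions) == 0)
    fd_stop("need at least one model prediction", "fd_value_error")
  n <- unique(vapply(predictions, length, integer(1)))
  if (length(n) != 1)
    fd_stop("prediction vectors differ in length", "fd_shape_error")
  pm <- do.call(cbind, lapply(predictions, as.numeric))
  if (rule == "soft") {
    rowMeans(pm) > 0.5
  } else {
    pos <- rowSums(pm > 0.5)
    pos > ncol(pm) / 2
  }
}

#' Predict a foci mask for an image
#'
#' Applies the model's filter bank, the stored z-scoring + PCA projection,
#' each requested member model and the voting rule; the resulting boolean
#' mask is restricted to the ROI when one is given.
#'
#' @param model an `fd_foci_model` trained on bank+PCA features (its
#'   `pca` and `bank_config` must be set).
#' @param foci a [channel_image()] of the foci channel.
#' @param roi optional `fd_nucleus_roi` restricting the mask.
#' @param models voting members (default: all fitted components).
#' @param rule voting rule override (default: the spec's).
#' @return an [label_mask()] (logical).
#' @export
predict_mask <- function(model, foci, roi = NULL, models = NULL, rule = NULL) {
  if (is.null(model$pca) || is.null(model$bank_config))
    fd_stop("model lacks preprocessing (pca/bank_config); train it on a pixel set built by build_training_set()",
            "fd_value_error")
  stack <- apply_bank(foci, model$bank_config)
  feat <- pca_project(stack_to_matrix(stack), model$pca)
  pr <- predict_pixel_prob(model, feat, models)
  rule <- if (is.null(rule)) model$spec$voting_rule else rule
  pos <- vote(pr, rule)
  px <- if (inherits(foci, "fd_channel_image")) foci$pixels else foci
  m <- matrix(pos, nrow(px), ncol(px))
  if (!is.null(roi)) m <- m & roi$mask
  meta <- if (inherits(foci, "fd_channel_image")) foci$meta else NULL
  label_mask(m, meta)
}

## ---- persistence -----------------------------------------------------------

#' Save a trained model bundle to JSON
#'
#' The bundle stores the spec, bank configuration, PCA (means, scales,
#' components), any scalers and all fitted components at full numeric
#' precision, with a format version.
#'
#' @param model an `fd_foci_model`.
#' @param path destination path (.json).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attr(x, "class") <- NULL
    }
    x
  }
  bundle <- list(format = "focidetect-model", version = 1L, model = strip(unclass(model)))
  jsonlite::write_json(bundle, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a model bundle written by [save_model()]
#' @param path JSON bundle path.
#' @return an `fd_foci_model`.
#' @export
load_model <- function(path) {
  bundle <- jsonlite::fromJSON(path, simplifyMatrix = TRUE,
                               simplifyDataFrame = FALSE)
  if (!identical(bundle$format, "focidetect-model"))
    fd_stop("not a focidetect model bundle", "fd_format_error")
  m <- bundle$model
  m$spec <- structure(m$spec, class = "fd_classifier_spec")
  if (length(m$bank_config) == 0) m$bank_config <- NULL
  if (!is.null(m$bank_config))
    m$bank_config <- structure(m$bank_config, class = "fd_filter_bank_config")
  if (length(m$pca) == 0) m$pca <- NULL
  if (!is.null(m$pca)) {
    if (!is.matrix(m$pca$components))
      m$pca$components <- matrix(m$pca$components, nrow = 1)
    m$pca <- structure(m$pca, class = "fd_pca")
  }
  fixup <- function(comp) {
    if (!is.list(comp)) return(comp)
    if (!is.null(comp$kind) && comp$kind == "mlp") {
      comp$W1 <- as.matrix(comp$W1)
      comp$W2 <- matrix(unlist(comp$W2), ncol = 1)
    }
    if (!is.null(comp$kind) && comp$kind == "cnb")
      comp$flp <- as.matrix(comp$flp)
    if (!is.null(comp$members))
      comp$members <- lapply(comp$members, fixup)
    if (!is.null(comp$trees))
      comp$trees <- lapply(comp$trees, as.matrix)
    comp
  }
  m$components <- lapply(m$components, fixup)
  structure(m, class = "fd_foci_model")
}
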