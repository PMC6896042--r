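# Two-level hierarchical SVM ensemble: per-family RBF classifiers with
# calibrated probability scores, stacked into a linear/RBF/sigmoid
# meta-ensemble combined by majority voting.

#' Cross-validation scheme
#'
#' @param n_folds number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param stratified stratify folds by class (default TRUE).
#' @param group_key optional per-sample grouping id (e.g. patient/slide); no
#'   group ever spans folds.
#' @return list of class `cv_scheme`.
#' @export
cv_scheme <- function(n_folds = 10L, seed = 1L, stratified = TRUE,
                      group_key = NULL) {
  structure(list(n_folds = as.integer(n_folds), seed = as.integer(seed),
                 stratified = stratified, group_key = group_key),
            class = "cv_scheme")
}

#' Deterministic (optionally stratified / group-aware) fold assignment
#' @param labels class labels.
#' @param scheme a [cv_scheme()].
#' @return integer vector of fold ids in `1 .. n_folds`.
#' @export
make_folds <- function(labels, scheme = cv_scheme()) {
  n <- length(labels)
  k <- min(scheme$n_folds, n)
  with_seed(scheme$seed, {
    fold <- integer(n)
    if (!is.null(scheme$group_key)) {
      groups <- as.character(scheme$group_key)
      ug <- sample(unique(groups))
      gf <- setNames(rep_len(seq_len(k), length(ug)), ug)
      fold <- unname(gf[groups])
    } else if (scheme$stratified) {
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      fold <- sample(rep_len(seq_len(k), n))
    }
    fold
  })
}

#' SVM hyperparameter grid
#'
#' Log2-spaced cost/gamma grids. The default grid is a reduced lattice
#' suited to the documented problem sizes; `full = TRUE` gives the wide
#' C in 2^-5..2^15, gamma in 2^-15..2^3 lattice.
#'
#' @param full use the wide grid.
#' @return list with `cost` and `gamma` vectors (sigmoid coef0 is fixed at 0).
#' @export
svm_grid <- function(full = FALSE) {
  if (full)
    list(cost = 2^seq(-5, 15, by = 2), gamma = 2^seq(-15, 3, by = 2))
  else
    list(cost = 2^c(-3, 0, 3, 6, 9, 12), gamma = 2^c(-9, -6, -3, 0, 3))
}

# ---- Platt sigmoid calibration ------------------------------------------

# Platt's sigmoid P(y=1|d) = 1/(1+exp(A d + B)) fitted by BFGS on the
# regularised NLL with Platt's smoothed targets; deterministic.
platt_fit <- function(dv, y1) {
  n1 <- sum(y1); n0 <- sum(!y1)
  t <- ifelse(y1, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  nll <- function(par) {
    z <- clamp(par[1] * dv + par[2], -35, 35)
    p <- 1 / (1 + exp(z))
    -sum(t * log(pmax(p, 1e-12)) + (1 - t) * log(pmax(1 - p, 1e-12)))
  }
  init <- c(A = -1, B = log((n0 + 1) / (n1 + 1)))
  fit <- optim(init, nll, method = "BFGS", control = list(maxit = 200))
  fit$par
}

platt_predict <- function(par, dv) {
  z <- clamp(par[1] * dv + par[2], -35, 35)
  1 / (1 + exp(z))
}

# ---- one feature-family SVM classifier ----------------------------------

#' Fit a calibrated SVM classifier on one feature family
#'
#' Features are z-scored (constant columns dropped with a warning); `(C,
#' gamma)` are grid-searched by stratified `calib_folds`-fold CV accuracy on
#' the supplied data only. Probabilities come from one-vs-rest binary SVMs
#' whose decision values are calibrated by a Platt sigmoid fitted on
#' out-of-fold decision values of the same inner CV, then normalised to sum
#' to one. Everything is deterministic given `seed`.
#'
#' @param X numeric matrix (samples x features).
#' @param y class labels (2 or 3 classes present).
#' @param grid an [svm_grid()], or a list with scalar `cost`/`gamma` to skip
#'   the search.
#' @param kernel `"radial"`, `"linear"` or `"sigmoid"`.
#' @param calib_folds inner folds for grid search and calibration.
#' @param seed fold seed.
#' @return object of class `glandpath_svm` with out-of-fold inner accuracy
#'   (`cv_accuracy`), mean top-class probability margin on the inner
#'   validation folds (`cv_margin`), chosen parameters and fitted models.
#' @export
fit_svm_family <- function(X, y, grid = svm_grid(), kernel = "radial",
                           calib_folds = 3L, seed = 1L) {
  X <- as.matrix(X)
  y <- factor(y)
  classes <- levels(y)
  if (length(unique(y)) < 2)
    stop("single-class input: cannot train a classifier", call. = FALSE)
  sds <- apply(X, 2, sd)
  keep <- which(is.finite(sds) & sds > 1e-12)
  if (length(keep) < ncol(X))
    warning(sprintf("dropping %d zero-variance feature(s)", ncol(X) - length(keep)))
  if (length(keep) == 0) stop("no informative features", call. = FALSE)
  ctr <- colMeans(X[, keep, drop = FALSE])
  scl <- sds[keep]
  Xs <- scale(X[, keep, drop = FALSE], center = ctr, scale = scl)

  combos <- if (kernel == "linear") {
    data.frame(cost = grid$cost, gamma = 1)
  } else {
    expand.grid(cost = grid$cost, gamma = grid$gamma,
                KEEP.OUT.ATTRS = FALSE)
  }
  folds <- make_folds(y, cv_scheme(calib_folds, seed = seed))
  k_eff <- max(folds)

  fit_one <- function(Xtr, ytr, cost, gamma) {
    e1071::svm(x = Xtr, y = ytr, type = "C-classification", kernel = kernel,
               cost = cost, gamma = gamma, coef0 = 0, scale = FALSE)
  }
  cv_acc <- function(cost, gamma) {
    hits <- 0L
    for (f in seq_len(k_eff)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2) next
      m <- fit_one(Xs[tr, , drop = FALSE], droplevels(y[tr]), cost, gamma)
      p <- predict(m, Xs[!tr, , drop = FALSE])
      hits <- hits + sum(as.character(p) == as.character(y[!tr]))
    }
    hits / length(y)
  }
  accs <- mapply(cv_acc, combos$cost, combos$gamma)
  best <- which.max(accs)     # ties: first combo in deterministic order
  cost <- combos$cost[best]; gamma <- combos$gamma[best]

  # one-vs-rest binaries with Platt calibration on inner out-of-fold
  # decision values; also yields the inner-CV probability margin
  binaries <- list()
  oof_prob <- matrix(NA_real_, nrow(Xs), length(classes),
                     dimnames = list(NULL, classes))
  for (cl in classes) {
    ybin <- factor(ifelse(y == cl, "pos", "neg"), levels = c("pos", "neg"))
    oof_dv <- rep(NA_real_, nrow(Xs))
    for (f in seq_len(k_eff)) {
      tr <- folds != f
      if (length(unique(ybin[tr])) < 2) next
      m <- fit_one(Xs[tr, , drop = FALSE], ybin[tr], cost, gamma)
      pv <- predict(m, Xs[!tr, , drop = FALSE], decision.values = TRUE)
      oof_dv[!tr] <- as.numeric(attr(pv, "decision.values"))
    }
    ok <- !is.na(oof_dv)
    par <- platt_fit(oof_dv[ok], (y == cl)[ok])
    full <- fit_one(Xs, ybin, cost, gamma)
    binaries[[cl]] <- list(model = full, platt = par)
    oof_prob[ok, cl] <- platt_predict(par, oof_dv[ok])
  }
  oof_prob[is.na(oof_prob)] <- 1 / length(classes)
  oof_prob <- oof_prob / rowSums(oof_prob)
  margin <- mean(apply(oof_prob, 1, function(r) {
    s <- sort(r, decreasing = TRUE); s[1] - s[2]
  }))

  structure(list(classes = classes, kernel = kernel,
                 cost = cost, gamma = gamma,
                 center = ctr, scale = scl, keep = keep,
                 binaries = binaries,
                 cv_accuracy = accs[best], cv_margin = margin,
                 grid_accuracies = accs, oof_prob = oof_prob,
                 n_features = ncol(X)),
            class = "glandpath_svm")
}

#' Predict calibrated class probabilities
#'
#' @param object a `glandpath_svm`.
#' @param newdata numeric matrix with the training feature layout.
#' @param ... unused.
#' @return matrix (samples x classes) of probabilities, rows summing to 1.
#' @export
predict.glandpath_svm <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$n_features)
    stop("feature layout mismatch: expected ", object$n_features,
         " columns, got ", ncol(X), call. = FALSE)
  Xs <- scale(X[, object$keep, drop = FALSE],
              center = object$center, scale = object$scale)
  probs <- vapply(object$classes, function(cl) {
    b <- object$binaries[[cl]]
    pv <- predict(b$model, Xs, decision.values = TRUE)
    platt_predict(b$platt, as.numeric(attr(pv, "decision.values")))
  }, numeric(nrow(Xs)))
  probs <- matrix(probs, nrow = nrow(Xs),
                  dimnames = list(NULL, object$classes))
  rs <- rowSums(probs)
  rs[rs < 1e-12] <- 1
  probs <- probs / rs
  flat <- rowSums(probs) < 1e-12
  probs[flat, ] <- 1 / length(object$classes)
  probs
}

prob_to_label <- function(prob, classes) {
  classes[max.col(prob, ties.method = "first")]
}

# ---- bundle plumbing -----------------------------------------------------

#' Assemble feature-family design matrices from bundles
#' @param bundles list of `feature_bundle`.
#' @return list with `image` (n x 11), `gland`, `patch` (list of per-subset
#'   n x 11 matrices), `labels`, `layout_hash`.
#' @export
bundles_to_matrices <- function(bundles) {
  stopifnot(length(bundles) >= 1)
  hashes <- vapply(bundles, function(b)
    config_hash(list(names(b$image_features), names(b$gland_features),
                     dim(b$patch_features))), "")
  if (length(unique(hashes)) != 1)
    stop("schema error: bundles have mismatched feature layouts", call. = FALSE)
  Ximg <- t(vapply(bundles, function(b) b$image_features,
                   numeric(length(bundles[[1]]$image_features))))
  Xgld <- t(vapply(bundles, function(b) b$gland_features,
                   numeric(length(bundles[[1]]$gland_features))))
  n_sub <- nrow(bundles[[1]]$patch_features)
  Xpat <- lapply(seq_len(n_sub), function(j)
    t(vapply(bundles, function(b) b$patch_features[j, ], numeric(11))))
  list(image = Ximg, gland = Xgld, patch = Xpat,
       labels = vapply(bundles, function(b) as.character(b$label), ""),
       layout_hash = hashes[1])
}

#' Select the patch weak classifier with the highest confidence
#'
#' Confidence is the mean top-class probability margin (top minus runner-up)
#' over the classifier's validation-fold probability scores; ties go to the
#' lowest subset index.
#'
#' @param weak_scores list of probability matrices, one per weak classifier.
#' @param margins optional numeric vector of precomputed confidences.
#' @return list with `index` of the selected classifier and its `score`
#'   matrix.
#' @export
select_patch_score <- function(weak_scores, margins = NULL) {
  if (length(weak_scores) < 1)
    stop("need at least one weak classifier", call. = FALSE)
  if (is.null(margins)) {
    margins <- vapply(weak_scores, function(P)
      mean(apply(P, 1, function(r) {
        s <- sort(r, decreasing = TRUE)
        if (length(s) > 1) s[1] - s[2] else s[1]
      })), numeric(1))
  }
  idx <- which.max(margins)   # which.max takes the first maximum
  list(index = idx, score = weak_scores[[idx]], margins = margins)
}

#' Majority vote over classifier predictions
#'
#' Returns the modal label per sample; ties are broken by the highest summed
#' class probability across voters, then by class order.
#'
#' @param predictions character/factor matrix (samples x voters).
#' @param probabilities list (one per voter) of probability matrices with
#'   identical class columns.
#' @param classes class order used for final tie-breaks.
#' @return character vector of final labels.
#' @export
majority_vote <- function(predictions, probabilities = NULL, classes = NULL) {
  predictions <- as.matrix(predictions)
  if (ncol(predictions) < 1 || nrow(predictions) < 1)
    stop("empty voter list", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(as.character(predictions)))
  n <- nrow(predictions)
  out <- character(n)
  psum <- NULL
  if (!is.null(probabilities))
    psum <- Reduce(`+`, lapply(probabilities, function(P)
      P[, classes, drop = FALSE]))
  for (i in seq_len(n)) {
    votes <- table(factor(as.character(predictions[i, ]), levels = classes))
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) { out[i] <- top; next }
    if (!is.null(psum)) {
      sub <- psum[i, top]
      top <- top[sub == max(sub)]
    }
    out[i] <- top[1]   # class order
  }
  out
}

# ---- hierarchical model --------------------------------------------------

#' Train the full two-level hierarchical model
#'
#' Level 1 fits an RBF-SVM per feature family (image, gland, and one weak
#' classifier per patch subset, of which the most confident is selected).
#' Level-2 meta-features are level-1 probability scores obtained by an
#' internal `meta_folds`-fold cross-validation of the training data (so the
#' meta-classifiers never see resubstitution probabilities); the meta level
#' comprises linear, RBF and sigmoid SVMs whose majority vote is the final
#' prediction. No statistic (scaling, grid choice, calibration, subset
#' selection) uses data outside `bundles`.
#'
#' @param bundles list of `feature_bundle` with labels.
#' @param scheme a [cv_scheme()]; its seed drives all internal randomness.
#' @param grid an [svm_grid()].
#' @param meta_folds internal folds producing meta-features (default 5).
#' @param patch_mode `"select"` uses the single most confident weak patch
#'   classifier; `"vote"` averages all weak classifiers' scores.
#' @return object of class `hierarchical_model`.
#' @export
fit_hierarchical <- function(bundles, scheme = cv_scheme(), grid = svm_grid(),
                             meta_folds = 5L, patch_mode = c("select", "vote")) {
  patch_mode <- match.arg(patch_mode)
  mats <- bundles_to_matrices(bundles)
  y <- factor(mats$labels)
  classes <- levels(y)
  if (length(classes) < 2) stop("need >= 2 classes", call. = FALSE)
  seed <- scheme$seed

  fam <- function(X, sd_off) suppressWarnings(
    fit_svm_family(X, y, grid, "radial", seed = seed + sd_off))
  level1 <- list(image = fam(mats$image, 11L),
                 gland = fam(mats$gland, 13L),
                 patch = lapply(seq_along(mats$patch), function(j)
                   fam(mats$patch[[j]], 17L + j)))
  sel <- select_patch_score(lapply(level1$patch, `[[`, "oof_prob"),
                            margins = vapply(level1$patch, `[[`, 0, "cv_margin"))

  # fixed hyper-parameters reused in the internal CV (chosen on training
  # data only)
  fixed <- lapply(c(level1["image"], level1["gland"]), function(m)
    list(cost = m$cost, gamma = m$gamma))
  fixed$patch <- lapply(level1$patch, function(m)
    list(cost = m$cost, gamma = m$gamma))

  inner <- make_folds(y, cv_scheme(meta_folds, seed = seed + 101L))
  k_eff <- max(inner)
  P1 <- matrix(NA_real_, length(y), length(classes), dimnames = list(NULL, classes))
  P2 <- P1; P3 <- P1
  for (f in seq_len(k_eff)) {
    tr <- inner != f
    if (length(unique(y[tr])) < 2) next
    f_img <- suppressWarnings(fit_svm_family(
      mats$image[tr, , drop = FALSE], y[tr], fixed$image, "radial",
      seed = seed + 211L + f))
    f_gld <- suppressWarnings(fit_svm_family(
      mats$gland[tr, , drop = FALSE], y[tr], fixed$gland, "radial",
      seed = seed + 223L + f))
    P1[!tr, ] <- predict(f_img, mats$image[!tr, , drop = FALSE])[, classes]
    P3[!tr, ] <- predict(f_gld, mats$gland[!tr, , drop = FALSE])[, classes]
    if (patch_mode == "select") {
      j <- sel$index
      f_pat <- suppressWarnings(fit_svm_family(
        mats$patch[[j]][tr, , drop = FALSE], y[tr], fixed$patch[[j]],
        "radial", seed = seed + 227L + f))
      P2[!tr, ] <- predict(f_pat, mats$patch[[j]][!tr, , drop = FALSE])[, classes]
    } else {
      acc <- 0
      for (j in seq_along(mats$patch)) {
        f_pat <- suppressWarnings(fit_svm_family(
          mats$patch[[j]][tr, , drop = FALSE], y[tr], fixed$patch[[j]],
          "radial", seed = seed + 227L + f + 31L * j))
        acc <- acc + predict(f_pat, mats$patch[[j]][!tr, , drop = FALSE])[, classes]
      }
      P2[!tr, ] <- acc / length(mats$patch)
    }
  }
  fill_uniform <- function(P) {
    bad <- !stats::complete.cases(P)
    P[bad, ] <- 1 / ncol(P)
    P
  }
  P1 <- fill_uniform(P1); P2 <- fill_uniform(P2); P3 <- fill_uniform(P3)
  meta <- cbind(P1, P2, P3)
  if (all(apply(meta, 2, sd) < 1e-12)) {
    # cohort too small for the internal CV (every fold degenerate): fall
    # back to resubstitution meta-features rather than failing the batch
    warning("internal CV degenerate; using resubstitution meta-features")
    j <- sel$index
    meta <- cbind(predict(level1$image, mats$image)[, classes, drop = FALSE],
                  predict(level1$patch[[j]], mats$patch[[j]])[, classes, drop = FALSE],
                  predict(level1$gland, mats$gland)[, classes, drop = FALSE])
  }
  colnames(meta) <- paste0(rep(c("img_", "pat_", "gld_"), each = length(classes)),
                           rep(classes, 3))

  level2 <- list(
    linear = suppressWarnings(fit_svm_family(meta, y, grid, "linear",
                                             seed = seed + 307L)),
    radial = suppressWarnings(fit_svm_family(meta, y, grid, "radial",
                                             seed = seed + 311L)),
    sigmoid = suppressWarnings(fit_svm_family(meta, y, grid, "sigmoid",
                                              seed = seed + 313L)))

  structure(list(level1 = level1, level2 = level2,
                 selected_subset = sel$index, patch_mode = patch_mode,
                 classes = classes, layout_hash = mats$layout_hash,
                 seed = seed, meta_colnames = colnames(meta)),
            class = "hierarchical_model")
}

#' Predict with a hierarchical model
#'
#' @param object a `hierarchical_model`.
#' @param bundles list of `feature_bundle` with the training feature layout.
#' @param ... unused.
#' @return list with `label` (majority-vote final labels), `meta`
#'   (meta-feature matrix), `per_kernel` (labels per meta kernel),
#'   `probabilities` (per-kernel probability matrices), `prob` (mean
#'   meta-ensemble probabilities).
#' @export
predict.hierarchical_model <- function(object, bundles, ...) {
  mats <- bundles_to_matrices(bundles)
  if (mats$layout_hash != object$layout_hash)
    stop("schema error: bundle feature layout differs from training layout",
         call. = FALSE)
  classes <- object$classes
  P1 <- predict(object$level1$image, mats$image)[, classes, drop = FALSE]
  P3 <- predict(object$level1$gland, mats$gland)[, classes, drop = FALSE]
  if (object$patch_mode == "select") {
    j <- object$selected_subset
    P2 <- predict(object$level1$patch[[j]], mats$patch[[j]])[, classes, drop = FALSE]
  } else {
    P2 <- Reduce(`+`, lapply(seq_along(object$level1$patch), function(j)
      predict(object$level1$patch[[j]], mats$patch[[j]])[, classes, drop = FALSE])) /
      length(object$level1$patch)
  }
  meta <- cbind(P1, P2, P3)
  colnames(meta) <- object$meta_colnames
  probs <- lapply(object$level2, function(m) predict(m, meta)[, classes, drop = FALSE])
  preds <- vapply(probs, prob_to_label, character(nrow(meta)), classes = classes)
  preds <- matrix(preds, nrow = nrow(meta),
                  dimnames = list(NULL, names(object$level2)))
  final <- majority_vote(preds, probs, classes)
  list(label = final, meta = meta, per_kernel = preds,
       probabilities = probs,
       prob = Reduce(`+`, probs) / length(probs))
}

#' Cross-validate the full two-level pipeline
#'
#' The entire pipeline (scaling, grid search, calibration, patch-classifier
#' selection, meta-training) is re-fitted inside each outer training fold;
#' predictions on the held-out folds are pooled and scored.
#'
#' @param bundles list of labelled `feature_bundle`.
#' @param scheme outer [cv_scheme()] (default 10-fold).
#' @param grid an [svm_grid()].
#' @param meta_folds internal folds for meta-feature construction.
#' @param positive positive class for binary metrics (defaults to the last
#'   class level).
#' @return list with `predictions` (data.frame: truth, prediction, fold,
#'   per-class ensemble probabilities), `report` (a
#'   [classification_report()]), `per_kernel_accuracy`, `ensemble_accuracy`,
#'   `folds`.
#' @export
cross_validate <- function(bundles, scheme = cv_scheme(), grid = svm_grid(),
                           meta_folds = 5L, positive = NULL) {
  labels <- vapply(bundles, function(b) as.character(b$label), "")
  y <- factor(labels)
  classes <- levels(y)
  folds <- make_folds(labels, scheme)
  pred <- character(length(labels))
  per_kernel <- matrix(NA_character_, length(labels), 3,
                       dimnames = list(NULL, c("linear", "radial", "sigmoid")))
  prob <- matrix(NA_real_, length(labels), length(classes),
                 dimnames = list(NULL, classes))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    model <- fit_hierarchical(bundles[tr],
                              cv_scheme(scheme$n_folds,
                                        seed = scheme$seed + 1000L * f,
                                        stratified = scheme$stratified),
                              grid, meta_folds)
    out <- predict(model, bundles[!tr])
    pred[!tr] <- out$label
    per_kernel[!tr, ] <- out$per_kernel
    prob[!tr, ] <- out$prob[, classes]
  }
  rep <- classification_report(labels, pred, prob, positive = positive,
                               folds = folds)
  list(predictions = data.frame(truth = labels, prediction = pred,
                                fold = folds, prob,
                                check.names = FALSE),
       report = rep,
       per_kernel_accuracy = colMeans(per_kernel == labels),
       ensemble_accuracy = mean(pred == labels),
       folds = folds)
}

#' Train on one cohort, test on another
#'
#' Fits the entire pipeline (including scaling, grid search, calibration and
#' meta-training) on the training cohort only, then scores predictions on
#' the independent test cohort. Feature layouts must match exactly.
#'
#' @param train_bundles,test_bundles labelled `feature_bundle` lists.
#' @param grid an [svm_grid()].
#' @param scheme internal [cv_scheme()] for the training-cohort machinery.
#' @param positive positive class for binary metrics.
#' @return list with `report`, `predictions`, and the fitted `model`.
#' @export
cross_dataset_evaluate <- function(train_bundles, test_bundles,
                                   grid = svm_grid(), scheme = cv_scheme(),
                                   positive = NULL) {
  model <- fit_hierarchical(train_bundles, scheme, grid)
  out <- predict(model, test_bundles)
  truth <- vapply(test_bundles, function(b) as.character(b$label), "")
  rep <- classification_report(truth, out$label,
                               out$prob[, model$classes, drop = FALSE],
                               positive = positive)
  list(report = rep,
       predictions = data.frame(truth = truth, prediction = out$label,
                                out$prob, check.names = FALSE),
       model = model)
}
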