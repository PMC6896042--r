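# Segmentation and classification scoring, ROC/AUC, and feature-comparison
# statistics (Wilcoxon rank-sum with Bonferroni correction).

#' Pixelwise confusion counts of a predicted mask against ground truth
#'
#' @param pred_mask,truth_mask logical/0-1 matrices of identical size.
#' @return named list of class `confusion_counts`: `tp`, `fp`, `tn`, `fn`.
#' @export
pixel_confusion <- function(pred_mask, truth_mask) {
  if (!identical(dim(pred_mask), dim(truth_mask)))
    stop("mask dimensions differ", call. = FALSE)
  p <- pred_mask > 0.5; t <- truth_mask > 0.5
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t)),
            class = "confusion_counts")
}

#' Segmentation metrics from confusion counts
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), accuracy (tp+tn)/total,
#' Dice 2tp/(2tp+fp+fn), Jaccard tp/(tp+fp+fn), and the F-score (harmonic
#' mean of precision and recall, which for pixel counts equals the Dice).
#' Metrics with a zero denominator are returned as `NaN` and listed in the
#' `undefined` attribute.
#'
#' @param counts a `confusion_counts` (or list with tp/fp/tn/fn).
#' @return named numeric vector of class `segmentation_score`.
#' @export
segmentation_score <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total == 0) stop("all-zero confusion counts", call. = FALSE)
  safe <- function(num, den) if (den > 0) num / den else NaN
  prec <- safe(tp, tp + fp); rec <- safe(tp, tp + fn)
  f <- if (is.finite(prec) && is.finite(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NaN
  out <- c(sensitivity = safe(tp, tp + fn),
           specificity = safe(tn, tn + fp),
           accuracy = (tp + tn) / total,
           dice = safe(2 * tp, 2 * tp + fp + fn),
           jaccard = safe(tp, tp + fp + fn),
           f_score = f)
  attr(out, "undefined") <- names(out)[!is.finite(out)]
  class(out) <- "segmentation_score"
  out
}

#' Match segmented glands to ground-truth glands and score the overlap
#'
#' Each ground-truth gland id is matched to the predicted gland with the
#' largest pixel overlap; its Dice is computed on that pair (0 when nothing
#' overlaps). Also reports the whole-image binary (gland vs background)
#' scores.
#'
#' @param result a `segmentation_result` (or an integer label mask).
#' @param truth_mask integer ground-truth label mask (0 = background).
#' @return list with `per_gland` (data.frame: truth_id, matched_pred, dice,
#'   jaccard), `n_true`, `n_pred`, `binary` (a [segmentation_score()]).
#' @export
gland_overlap_scores <- function(result, truth_mask) {
  pred_lab <- if (inherits(result, "segmentation_result"))
    result$gland_label_mask else result
  if (!identical(dim(pred_lab), dim(truth_mask)))
    stop("mask dimensions differ", call. = FALSE)
  tids <- setdiff(sort(unique(as.vector(truth_mask))), 0L)
  rows <- lapply(tids, function(tid) {
    tmask <- truth_mask == tid
    inside <- pred_lab[tmask]
    inside <- inside[inside > 0]
    if (length(inside) == 0)
      return(data.frame(truth_id = tid, matched_pred = NA_integer_,
                        dice = 0, jaccard = 0))
    pid <- as.integer(names(which.max(table(inside))))
    pmask <- pred_lab == pid
    inter <- sum(pmask & tmask)
    dice <- 2 * inter / (sum(pmask) + sum(tmask))
    data.frame(truth_id = tid, matched_pred = pid,
               dice = dice, jaccard = dice / (2 - dice))
  })
  list(per_gland = do.call(rbind, rows),
       n_true = length(tids),
       n_pred = length(setdiff(unique(as.vector(pred_lab)), 0L)),
       binary = segmentation_score(pixel_confusion(pred_lab > 0,
                                                   truth_mask > 0)))
}

#' Multi-class Matthews correlation coefficient
#'
#' Gorodkin's generalisation from the confusion matrix; for two classes it
#' reduces to the usual binary MCC and is invariant to swapping the class
#' roles.
#'
#' @param truth,pred label vectors.
#' @return scalar in `[-1, 1]` (0 when a marginal is degenerate).
#' @export
mcc_score <- function(truth, pred) {
  classes <- sort(unique(c(as.character(truth), as.character(pred))))
  C <- table(factor(truth, classes), factor(pred, classes))
  s <- sum(C); c0 <- sum(diag(C))
  tk <- rowSums(C); pk <- colSums(C)
  num <- c0 * s - sum(pk * tk)
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  if (den == 0) return(0)
  num / den
}

#' ROC curve points and trapezoidal AUC
#'
#' @param truth01 logical/0-1 vector (1 = positive).
#' @param score numeric scores (higher = more positive).
#' @return list with `points` (data.frame fpr/tpr/threshold, from (0,0) to
#'   (1,1)) and `auc` (trapezoidal rule).
#' @export
roc_curve <- function(truth01, score) {
  truth01 <- as.logical(truth01)
  np <- sum(truth01); nn <- sum(!truth01)
  if (np == 0 || nn == 0) stop("need both classes for a ROC", call. = FALSE)
  th <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(score >= t & truth01) / np, 0)
  fpr <- vapply(th, function(t) sum(score >= t & !truth01) / nn, 0)
  pts <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
                    threshold = c(Inf, th, -Inf))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Classification metrics, ROC/AUC and per-fold breakdown
#'
#' Binary problems report sensitivity/specificity for the designated
#' positive class; 3-class problems report macro-averaged one-vs-rest
#' sensitivity and specificity (micro-averaging available). MCC uses the
#' generalised multi-class formula. When class probabilities are supplied, a
#' one-vs-rest ROC/AUC is computed per class by the trapezoidal rule over
#' the pooled scores; without probabilities the ROC is skipped with a
#' warning.
#'
#' @param truth,pred label vectors.
#' @param prob optional probability matrix with class columns.
#' @param positive positive class for binary metrics (default: last class).
#' @param average `"macro"` or `"micro"` one-vs-rest averaging for
#'   multi-class sensitivity/specificity.
#' @param folds optional fold ids for a per-fold accuracy breakdown.
#' @return object of class `classification_report`.
#' @export
classification_report <- function(truth, pred, prob = NULL, positive = NULL,
                                  average = c("macro", "micro"), folds = NULL) {
  average <- match.arg(average)
  truth <- as.character(truth); pred <- as.character(pred)
  classes <- sort(unique(truth))
  if (length(classes) < 2)
    stop("need at least 2 classes in the ground truth", call. = FALSE)
  acc <- mean(truth == pred)

  ovr <- function(cl) {
    tp <- sum(truth == cl & pred == cl); fn <- sum(truth == cl & pred != cl)
    fp <- sum(truth != cl & pred == cl); tn <- sum(truth != cl & pred != cl)
    c(tp = tp, fn = fn, fp = fp, tn = tn)
  }
  if (length(classes) == 2) {
    positive <- positive %||% classes[length(classes)]
    cc <- ovr(positive)
    sens <- cc["tp"] / max(cc["tp"] + cc["fn"], 1)
    spec <- cc["tn"] / max(cc["tn"] + cc["fp"], 1)
  } else {
    tab <- vapply(classes, ovr, numeric(4))
    if (average == "macro") {
      sens <- mean(tab["tp", ] / pmax(tab["tp", ] + tab["fn", ], 1))
      spec <- mean(tab["tn", ] / pmax(tab["tn", ] + tab["fp", ], 1))
    } else {
      sens <- sum(tab["tp", ]) / max(sum(tab["tp", ] + tab["fn", ]), 1)
      spec <- sum(tab["tn", ]) / max(sum(tab["tn", ] + tab["fp", ]), 1)
    }
  }

  rocs <- NULL
  if (!is.null(prob)) {
    prob <- as.matrix(prob)
    rocs <- lapply(classes, function(cl) {
      if (!cl %in% colnames(prob)) return(NULL)
      roc_curve(truth == cl, prob[, cl])
    })
    names(rocs) <- classes
  } else {
    warning("no probabilities supplied; ROC/AUC skipped")
  }

  per_fold <- NULL
  if (!is.null(folds))
    per_fold <- aggregate(truth == pred, by = list(fold = folds), FUN = mean)

  structure(list(accuracy = acc,
                 sensitivity = unname(sens), specificity = unname(spec),
                 mcc = mcc_score(truth, pred),
                 auc = if (!is.null(rocs))
                   vapply(rocs, function(r) if (is.null(r)) NA_real_ else r$auc,
                          0) else NULL,
                 roc = rocs, per_fold = per_fold,
                 classes = classes, positive = positive,
                 n = length(truth)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("classification report (n = %d, classes: %s)\n", x$n,
              paste(x$classes, collapse = ", ")))
  cat(sprintf("  accuracy    %.4f\n  sensitivity %.4f\n  specificity %.4f\n  mcc         %.4f\n",
              x$accuracy, x$sensitivity, x$specificity, x$mcc))
  if (!is.null(x$auc))
    cat("  auc         ",
        paste(sprintf("%s=%.4f", names(x$auc), x$auc), collapse = " "), "\n")
  invisible(x)
}

#' Wilcoxon rank-sum feature comparison with Bonferroni correction
#'
#' Each feature column is compared between the two groups with a two-sided
#' Wilcoxon rank-sum test (exact null when both groups have at most 10
#' observations and no ties; normal approximation with tie correction
#' otherwise). Raw p-values are Bonferroni-multiplied by `n_tests`.
#' Constant pooled features get p = 1 with a flag.
#'
#' @param values numeric matrix or data.frame (samples x features).
#' @param groups two-level factor/character vector over samples.
#' @param n_tests Bonferroni multiplier (default: number of features).
#' @return list with `comparisons` (data.frame: feature, raw_p, corrected_p,
#'   flag) and `boxplot_data` (tidy data.frame: feature, group, value).
#' @export
compare_features <- function(values, groups, n_tests = NULL) {
  values <- as.matrix(values)
  groups <- as.character(groups)
  glev <- unique(groups)
  if (length(glev) != 2) stop("exactly two groups required", call. = FALSE)
  if (min(table(groups)) < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("feature", seq_len(ncol(values)))
  n_tests <- n_tests %||% ncol(values)

  rows <- lapply(seq_len(ncol(values)), function(j) {
    v <- values[, j]
    x <- v[groups == glev[1]]; y <- v[groups == glev[2]]
    flag <- ""
    if (length(unique(v)) == 1) {
      p <- 1; flag <- "constant"
    } else {
      exact <- max(length(x), length(y)) <= 10 && !any(duplicated(v))
      p <- suppressWarnings(
        wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
    }
    data.frame(feature = colnames(values)[j], raw_p = p,
               corrected_p = min(1, p * n_tests), flag = flag,
               stringsAsFactors = FALSE)
  })
  bp <- data.frame(feature = rep(colnames(values), each = nrow(values)),
                   group = rep(groups, ncol(values)),
                   value = as.vector(values))
  list(comparisons = do.call(rbind, rows), boxplot_data = bp)
}

#' Feature weights of a fitted linear SVM
#'
#' Absolute weights of the (binary) linear meta-classifier, used to rank the
#' most discriminative features.
#'
#' @param fit a `glandpath_svm` with linear kernel (binary).
#' @return named numeric vector of weights on the scaled feature space.
#' @export
linear_svm_weights <- function(fit) {
  stopifnot(inherits(fit, "glandpath_svm"), fit$kernel == "linear")
  b <- fit$binaries[[1]]$model
  w <- as.numeric(t(b$coefs) %*% b$SV)
  names(w) <- colnames(b$SV)
  w
}
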