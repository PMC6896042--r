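test_that("pixel confusion counts match hand-tallied masks", {
  t <- matrix(FALSE, 20, 20); t[1:10, 1:10] <- TRUE         # 100 positives
  cc <- pixel_confusion(t, t)
  expect_equal(unclass(cc)[c("tp", "fp", "tn", "fn")],
               list(tp = 100, fp = 0, tn = 300, fn = 0))
  cc2 <- pixel_confusion(!t, t)
  expect_equal(cc2$tp, 0); expect_equal(cc2$tn, 0)
  p <- matrix(FALSE, 20, 20); p[1:10, 1:5] <- TRUE           # half coverage
  cc3 <- pixel_confusion(p, t)
  expect_equal(unclass(cc3)[c("tp", "fn", "fp")], list(tp = 50, fn = 50, fp = 0))
  expect_error(pixel_confusion(matrix(TRUE, 2, 2), t), "dimensions")
})

test_that("segmentation scores follow their defining formulas", {
  perfect <- segmentation_score(list(tp = 50, fp = 0, tn = 50, fn = 0))
  expect_true(all(perfect[c("sensitivity", "specificity", "accuracy",
                            "dice", "jaccard", "f_score")] == 1))
  sc <- segmentation_score(list(tp = 50, fn = 50, fp = 0, tn = 300))
  expect_equal(unname(sc["dice"]), 2 / 3)
  expect_equal(unname(sc["jaccard"]), 0.5)
  expect_error(segmentation_score(list(tp = 0, fp = 0, tn = 0, fn = 0)),
               "all-zero")
})

test_that("Dice-Jaccard identity holds on random confusion tables", {
  set.seed(101)
  for (i in 1:1000) {
    cts <- as.list(setNames(sample(0:200, 4, replace = TRUE),
                            c("tp", "fp", "tn", "fn")))
    if (cts$tp + cts$fp + cts$fn == 0 || sum(unlist(cts)) == 0) next
    sc <- segmentation_score(cts)
    if (is.finite(sc["dice"]))
      expect_equal(unname(sc["jaccard"]),
                   unname(sc["dice"] / (2 - sc["dice"])), tolerance = 1e-12)
  }
})

test_that("MCC matches its closed form and is swap-invariant", {
  truth <- c(rep("pos", 50), rep("neg", 50))
  pred <- c(rep("pos", 45), rep("neg", 5), rep("pos", 10), rep("neg", 40))
  expect_equal(mcc_score(truth, pred),
               (45 * 40 - 10 * 5) / sqrt((45 + 10) * (45 + 5) * (40 + 10) * (40 + 5)),
               tolerance = 1e-12)
  swap <- function(x) ifelse(x == "pos", "neg", "pos")
  expect_equal(mcc_score(swap(truth), swap(pred)), mcc_score(truth, pred))
  expect_equal(mcc_score(truth, truth), 1)

  set.seed(5)
  for (i in 1:200) {
    tr <- sample(c("a", "b"), 30, replace = TRUE)
    pr <- sample(c("a", "b"), 30, replace = TRUE)
    if (length(unique(tr)) < 2) next
    tp <- sum(tr == "b" & pr == "b"); tn <- sum(tr == "a" & pr == "a")
    fp <- sum(tr == "a" & pr == "b"); fn <- sum(tr == "b" & pr == "a")
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    expected <- if (den == 0) 0 else (tp * tn - fp * fn) / den
    expect_equal(mcc_score(tr, pr), expected, tolerance = 1e-12)
  }
})

test_that("ROC endpoints and AUC behave for perfect, reversed and chance scores", {
  y <- c(rep(1, 20), rep(0, 20))
  s <- c(seq(0.6, 1, length.out = 20), seq(0, 0.4, length.out = 20))
  expect_equal(roc_curve(y, s)$auc, 1)
  expect_equal(roc_curve(y, -s)$auc, 0)
  set.seed(31)
  y2 <- rep(c(0, 1), 100)
  s2 <- runif(200)
  auc <- roc_curve(y2, s2)$auc
  expect_gt(auc, 0.4); expect_lt(auc, 0.6)
})

test_that("trapezoidal AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  y <- rbinom(80, 1, 0.5)
  s <- y * 0.6 + rnorm(80, 0, 0.5)
  if (length(unique(y)) < 2) y[1] <- 1 - y[1]
  ours <- roc_curve(y, s)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("classification report covers binary and macro multi-class metrics", {
  truth <- c(rep("pos", 50), rep("neg", 50))
  pred <- truth
  rep1 <- suppressWarnings(classification_report(truth, pred, positive = "pos"))
  expect_equal(rep1$accuracy, 1); expect_equal(rep1$mcc, 1)

  set.seed(3)
  t3 <- sample(c("a", "b", "c"), 90, replace = TRUE)
  p3 <- t3; flip <- sample(90, 20); p3[flip] <- sample(c("a", "b", "c"), 20, TRUE)
  r3 <- suppressWarnings(classification_report(t3, p3))
  sens <- mean(vapply(c("a", "b", "c"), function(cl)
    sum(t3 == cl & p3 == cl) / sum(t3 == cl), 0))
  expect_equal(r3$sensitivity, sens, tolerance = 1e-12)
  expect_warning(classification_report(t3, p3), "ROC/AUC skipped")

  prob <- matrix(runif(90 * 3), 90, 3, dimnames = list(NULL, c("a", "b", "c")))
  r4 <- classification_report(t3, p3, prob)
  expect_length(r4$auc, 3L)
  expect_true(all(r4$auc >= 0 & r4$auc <= 1))
})

test_that("Wilcoxon comparisons reproduce exact enumeration and Bonferroni scaling", {
  vals <- cbind(f1 = c(1:5, 11:15))
  groups <- rep(c("g1", "g2"), each = 5)
  out <- compare_features(vals, groups, n_tests = 1)
  expect_equal(out$comparisons$raw_p, 2 / choose(10, 5), tolerance = 1e-12)

  # identical groups: statistic at the null centre
  same <- cbind(f1 = rep(c(3, 1, 4, 1, 5), 2))
  out2 <- compare_features(same, groups)
  expect_gte(out2$comparisons$raw_p, 0.99)

  out3 <- compare_features(cbind(f1 = c(1:5, 11:15)), groups, n_tests = 5)
  expect_equal(out3$comparisons$corrected_p,
               min(1, 5 * 2 / choose(10, 5)), tolerance = 1e-12)

  const <- cbind(f1 = rep(7, 10))
  out4 <- compare_features(const, groups)
  expect_equal(out4$comparisons$raw_p, 1)
  expect_equal(out4$comparisons$flag, "constant")
  expect_equal(nrow(out4$boxplot_data), 10L)
})

test_that("exact Wilcoxon agrees with full permutation enumeration (n <= 7)", {
  set.seed(23)
  for (t in 1:6) {
    n1 <- sample(3:7, 1); n2 <- sample(3:7, 1)
    x <- sample(seq(1, 100), n1); y <- sample(setdiff(seq(1, 100), x), n2)
    p_pkg <- compare_features(cbind(f = c(x, y)),
                              rep(c("g1", "g2"), c(n1, n2)))$comparisons$raw_p
    # enumerate all rank assignments of group 1
    ranks <- rank(c(x, y))
    W_obs <- sum(ranks[1:n1]) - n1 * (n1 + 1) / 2
    combs <- combn(n1 + n2, n1)
    Ws <- apply(combs, 2, function(idx) sum(ranks[idx]) - n1 * (n1 + 1) / 2)
    mu <- n1 * n2 / 2
    p_enum <- mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-9)
    expect_equal(p_pkg, p_enum, tolerance = 1e-10)
  }
})
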