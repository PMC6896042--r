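gauss_data <- function(n_per, sep, p = 6, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per * p, 0), ncol = p),
               matrix(rnorm(n_per * p, sep), ncol = p))
    list(X = X, y = rep(c("a", "b"), each = n_per))
  })
}

test_that("well-separated Gaussian classes are learned almost perfectly", {
  d <- gauss_data(50, 6)
  fit <- fit_svm_family(d$X, d$y, seed = 2L)
  expect_gte(fit$cv_accuracy, 0.98)
  P <- predict(fit, d$X)
  expect_equal(unname(rowSums(P)), rep(1, 100), tolerance = 1e-9)
  expect_true(all(P >= 0))
})

test_that("permuted labels land at chance accuracy", {
  d <- gauss_data(50, 6)
  yperm <- withr::with_seed(9L, sample(d$y))
  fit <- suppressWarnings(fit_svm_family(d$X, yperm, seed = 2L))
  expect_gte(fit$cv_accuracy, 0.35)
  expect_lte(fit$cv_accuracy, 0.65)
})

test_that("fitting is deterministic given the seed", {
  d <- gauss_data(20, 2)
  f1 <- fit_svm_family(d$X, d$y, seed = 7L)
  f2 <- fit_svm_family(d$X, d$y, seed = 7L)
  expect_identical(predict(f1, d$X), predict(f2, d$X))
  expect_identical(f1$cost, f2$cost)
})

test_that("single-class and zero-variance inputs are rejected or flagged", {
  d <- gauss_data(10, 2)
  expect_error(fit_svm_family(d$X, rep("a", 20)), "single-class")
  Xz <- cbind(d$X, 0)
  expect_warning(fit_svm_family(Xz, d$y, seed = 1L), "zero-variance")
})

test_that("patch-score selection prefers the widest probability margin", {
  s1 <- matrix(c(0.9, 0.1, 0.85, 0.15), 2, byrow = TRUE)
  s2 <- matrix(c(0.55, 0.45, 0.6, 0.4), 2, byrow = TRUE)
  sel <- select_patch_score(list(s2, s1))
  expect_equal(sel$index, 2L)
  expect_equal(select_patch_score(list(s2))$index, 1L)
  # exact margin tie: lowest index wins
  sel_tie <- select_patch_score(list(s1, s1))
  expect_equal(sel_tie$index, 1L)
})

test_that("majority voting follows mode, probability and class-order tie-breaks", {
  expect_equal(majority_vote(cbind(c("A"), c("A"), c("B"))), "A")
  expect_equal(majority_vote(cbind("A", "A", "A")), "A")
  probs <- list(matrix(c(0.2, 0.5, 0.3), 1, dimnames = list(NULL, c("A", "B", "C"))),
                matrix(c(0.1, 0.6, 0.3), 1, dimnames = list(NULL, c("A", "B", "C"))),
                matrix(c(0.3, 0.4, 0.3), 1, dimnames = list(NULL, c("A", "B", "C"))))
  expect_equal(majority_vote(cbind("A", "B", "C"), probs, c("A", "B", "C")), "B")
  expect_equal(majority_vote(cbind("A", "B", "C"), NULL, c("A", "B", "C")), "A")
  expect_error(majority_vote(matrix(character(0), 0, 0)), "empty voter")
})

test_that("meta level learns perfectly informative features and not uniform ones", {
  y <- rep(c("a", "b"), each = 20)
  onehot <- cbind(as.numeric(y == "a"), as.numeric(y == "b"))
  colnames(onehot) <- c("pa", "pb")
  for (kern in c("linear", "radial", "sigmoid")) {
    fit <- fit_svm_family(onehot, y, kernel = kern, seed = 3L)
    expect_equal(fit$cv_accuracy, 1)
  }
  flat <- matrix(0.5, 40, 2, dimnames = list(NULL, c("pa", "pb")))
  expect_error(suppressWarnings(fit_svm_family(flat, y, seed = 3L)),
               "no informative features")
})

test_that("models survive serialisation round trips", {
  d <- gauss_data(15, 4)
  fit <- fit_svm_family(d$X, d$y, seed = 5L)
  path <- tempfile(fileext = ".rds")
  saveRDS(fit, path)
  fit2 <- readRDS(path)
  expect_identical(predict(fit, d$X), predict(fit2, d$X))
})

test_that("folds are reproducible, stratified and group-aware", {
  y <- rep(c("a", "b"), each = 25)
  f1 <- make_folds(y, cv_scheme(5L, seed = 3L))
  f2 <- make_folds(y, cv_scheme(5L, seed = 3L))
  expect_identical(f1, f2)
  for (k in 1:5) expect_equal(sum(y[f1 == k] == "a"), 5)
  groups <- rep(1:10, each = 5)
  fg <- make_folds(rep("a", 50), cv_scheme(5L, seed = 1L, group_key = groups))
  for (g in unique(groups)) expect_length(unique(fg[groups == g]), 1L)
})

test_that("no training statistic leaks from held-out samples", {
  # canary: an extra feature informative ONLY in the held-out cohort must
  # not change what the model learns from the training cohort
  d <- gauss_data(20, 3, seed = 4)
  canary_tr <- matrix(0, 40, 1)
  Xtr <- cbind(d$X, canary_tr)
  fit_plain <- suppressWarnings(fit_svm_family(Xtr, d$y, seed = 6L))
  dte <- gauss_data(10, 3, seed = 8)
  canary_te <- matrix(as.numeric(dte$y == "a") * 100, 20, 1)
  Xte1 <- cbind(dte$X, 0)
  Xte2 <- cbind(dte$X, canary_te)
  # predictions must be driven by the training-fitted scaler/model only:
  # the dropped zero-variance canary column cannot influence them
  expect_identical(predict(fit_plain, Xte1), predict(fit_plain, Xte2))
})
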