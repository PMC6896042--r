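test_that("SGLD counts match hand-enumerated pairs", {
  cfg <- sgld_config(gray_levels = 2L)
  m0 <- compute_sgld(matrix(0L, 2, 2), cfg, angle = 0)
  expect_equal(dim(m0), c(2, 2))
  expect_equal(m0[1, 1], 1)
  expect_equal(sum(m0), 1)

  # rows alternating 0/1 along the row direction: horizontal pairs are all
  # (0,1) or (1,0) after symmetrisation
  g <- matrix(rep(c(0L, 1L), 4), nrow = 2, byrow = FALSE)
  g[] <- rep(c(0L, 1L), each = 2, times = 2)
  g <- matrix(c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L), nrow = 2)
  m <- compute_sgld(g, cfg, angle = 0)
  expect_equal(m[1, 2], m[2, 1])
  expect_gt(m[1, 2], 0)
  expect_true(isSymmetric(unclass(m)))

  m8 <- compute_sgld(matrix(0:7, 8, 8) %% 8L, sgld_config(), angle = 45)
  expect_equal(dim(m8), c(8, 8))
  expect_error(compute_sgld(matrix(0L, 1, 1), cfg, angle = 0), "no valid pairs")
  expect_error(compute_sgld(matrix(5L, 2, 2), cfg, angle = 0), "0 .. G-1")
})

test_that("Haralick features of degenerate and averaged matrices behave", {
  cfg <- sgld_config(gray_levels = 4L)
  m <- compute_sgld(matrix(2L, 5, 5), cfg, angle = 0)
  f <- haralick_features(m)
  expect_length(f, 11L)
  expect_equal(unname(f["entropy"]), 0)
  expect_equal(unname(f["energy"]), 1)
  expect_equal(unname(f["inertia"]), 0)
  # averaging identical matrices equals the single-matrix features
  expect_equal(haralick_features(list(m, m, m)), f)
  raw <- sgld_config(gray_levels = 4L, normalize = FALSE)
  expect_error(haralick_features(compute_sgld(matrix(2L, 5, 5), raw, 0)),
               "normalized")
})

test_that("all 11 features match the brute-force oracle on random rasters", {
  set.seed(7)
  worst <- 0
  for (t in 1:100) {
    g <- matrix(sample(0:7, 36, replace = TRUE), 6, 6)
    for (ang in c(0, 45, 90, 135)) {
      m <- compute_sgld(g, sgld_config(), ang)
      diff <- max(abs(haralick_features(m) - oracle_haralick(unclass(m))))
      worst <- max(worst, diff)
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("image features are rotation-invariant over the symmetric angle set", {
  s <- generate_phantom(phantom_config(seed = 21L))
  f1 <- image_features(s$image)
  rot <- array(0, dim = dim(s$image))
  for (ch in 1:3) rot[, , ch] <- t(s$image[, , ch])[, nrow(s$image):1]
  f2 <- image_features(rot)
  expect_equal(f1, f2, tolerance = 1e-10)
  flat <- array(128, dim = c(16, 16, 3))
  expect_equal(unname(image_features(flat)["entropy"]), 0)
})

test_that("patch tiling, pooling and subset determinism hold", {
  s <- generate_phantom(phantom_config(image_size = c(256L, 256L),
                                       gland_axes_range = c(20, 24),
                                       seed = 33L))
  pf <- patch_features(s$image, patch_size = 64L, n_subsets = 3L, seed = 5L)
  expect_equal(attr(pf, "n_tiles"), 16L)
  expect_equal(dim(pf), c(3L, 11L))

  # pooling every tile of a seam-free constant image equals whole-image
  # features
  flat <- array(200, dim = c(128, 128, 3))
  pfa <- patch_features(flat, patch_size = 64L, n_subsets = 1L,
                        subset_size = 4L, seed = 1L)
  expect_equal(unname(pfa[1, ]), unname(image_features(flat)),
               tolerance = 1e-12)

  p1 <- patch_features(s$image, 64L, n_subsets = 2L, seed = 9L)
  p2 <- patch_features(s$image, 64L, n_subsets = 2L, seed = 9L)
  p3 <- patch_features(s$image, 64L, n_subsets = 2L, seed = 10L)
  expect_identical(p1, p2)
  expect_false(identical(attr(p1, "subsets"), attr(p3, "subsets")))
  expect_error(patch_features(flat, patch_size = 256L), "smaller")
})
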