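test_that("gland selection keeps the k largest and smallest, deduplicated", {
  mk_res <- function(areas) {
    glands <- lapply(areas, function(a) {
      m <- matrix(FALSE, 40, 40); m[seq_len(a)] <- TRUE
      structure(list(region_mask = m), class = "gland")
    })
    structure(list(glands = glands), class = "segmentation_result")
  }
  res <- mk_res(seq(100, 1200, by = 100))   # 12 glands
  sel <- select_glands(res, 5L)
  expect_length(sel, 10L)
  expect_false(any(c(6L, 7L) %in% sel))     # the two median glands excluded
  expect_length(select_glands(mk_res(seq(100, 700, by = 100)), 5L), 7L)
  # ties at the cut resolved by gland id
  sel_tie <- select_glands(mk_res(rep(500, 12)), 5L)
  expect_identical(sel_tie, c(1:5, 8:12))
  expect_error(select_glands(structure(list(glands = list()),
                                       class = "segmentation_result"), 5L),
               "padding")
})

test_that("hand-built gland reproduces exact component ratios", {
  H <- 20L
  region <- matrix(FALSE, H, H); region[1:15, 1:20] <- TRUE  # 300 px
  lum <- matrix(FALSE, H, H); lum[3:6, 3:12] <- TRUE          # 40 px
  epi <- matrix(FALSE, H, H); epi[8:13, 1:20] <- TRUE         # 120 px
  nuc1 <- matrix(FALSE, H, H); nuc1[1:2, 1:15] <- TRUE        # 30 px
  nuc2 <- matrix(FALSE, H, H); nuc2[15, 1:20] <- TRUE; nuc2[14, 1:10] <- TRUE # 30
  gl <- structure(list(lumen_mask = lum, epithelium_mask = epi,
                       nuclei_masks = list(nuc1, nuc2),
                       region_mask = region,
                       lumen_centroid = mask_centroid(lum),
                       flags = character(0)),
                  class = "gland")
  f <- gland_features(gl)
  expect_equal(unname(f["ratio_lumen_gland"]), 40 / 300)
  expect_equal(unname(f["ratio_epithelium_gland"]), 120 / 300)
  expect_equal(unname(f["ratio_nuclei_gland"]), 60 / 300)
  expect_equal(unname(f["ratio_lumen_epithelium"]), 1 / 3)
  expect_equal(unname(f["area"]), 300)
})

test_that("circular regions have near-zero eccentricity and Euler number 1", {
  m <- raster_ellipse(c(60, 60), 30, 30, 20, 20)
  lum <- raster_ellipse(c(60, 60), 30, 30, 8, 8)
  gl <- structure(list(lumen_mask = lum, epithelium_mask = m & !lum,
                       nuclei_masks = list(), region_mask = m,
                       lumen_centroid = mask_centroid(lum),
                       flags = character(0)),
                  class = "gland")
  f <- gland_features(gl)
  expect_lt(unname(f["eccentricity"]), 0.1)
  expect_equal(unname(f["euler_number"]), 1)
  expect_true("too_few_nuclei" %in% attr(f, "flags"))
  expect_equal(unname(f["sd_dist_nuclei_to_lumen"]), 0)
})

test_that("ideal phantom glands show sub-pixel nuclear distance spread", {
  fx <- fixture_phantom()
  gl <- fx$seg$glands[[1]]
  f <- gland_features(gl)
  expect_lt(unname(f["sd_dist_nuclei_to_lumen"]), 1.5)
  expect_gt(unname(f["ratio_lumen_gland"]), 0.05)
})

test_that("feature bundles have stable dimensionality with few glands", {
  fx <- fixture_phantom()
  b <- extract_bundle(fx$sample$image, label = "normal",
                      segmentation = fx$seg, seed = 3L)
  expect_length(b$image_features, 11L)
  expect_length(b$gland_features, 10L * 19L)
  expect_equal(dim(b$patch_features), c(5L, 11L))
  expect_true("padded" %in% b$flags)   # 3 glands < 2k = 10 slots
  # a second image yields the same layout
  s2 <- generate_phantom(phantom_config(seed = 99L))
  b2 <- extract_bundle(s2$image, label = "poor", seed = 4L)
  expect_identical(names(b$gland_features), names(b2$gland_features))
  expect_identical(b$config_hash, b2$config_hash)
})
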