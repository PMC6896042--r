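test_that("empty phantom is pure stroma with an all-zero label mask", {
  s <- generate_phantom(phantom_config(n_glands = 0L, seed = 3L))
  expect_true(all(s$gland_label_mask == 0L))
  expect_equal(dim(s$image), c(192, 192, 3))
  # pink stroma dominates: green channel mean near the pink mean
  expect_lt(abs(mean(s$image[, , 2]) - 150), 10)
})

test_that("ideal glands have nuclei equidistant from the lumen centroid", {
  s <- generate_phantom(phantom_config(n_glands = 1L, deformation = 0,
                                       n_nuclei_per_gland = 12L, seed = 5L))
  cc <- s$components[[1]]
  cen <- mask_centroid(cc$lumen)
  d <- sqrt((cc$nucleus_centers[, "x"] - cen[["x"]])^2 +
              (cc$nucleus_centers[, "y"] - cen[["y"]])^2)
  expect_lt(sd(d), 1)
})

test_that("the generator is seed-deterministic and seed-sensitive", {
  cfg <- phantom_config(seed = 11L)
  s1 <- generate_phantom(cfg)
  s2 <- generate_phantom(cfg)
  expect_identical(s1, s2)
  s3 <- generate_phantom(phantom_config(seed = 12L))
  expect_false(identical(s1$image, s3$image))
  # different centres, not just different noise
  c1 <- mask_centroid(s1$gland_label_mask == 1)
  c3 <- mask_centroid(s3$gland_label_mask == 1)
  expect_false(isTRUE(all.equal(c1, c3, tolerance = 1e-6)))
})

test_that("component masks are disjoint and contained in the gland region", {
  for (d in c(0, 0.5, 1)) {
    s <- generate_phantom(phantom_config(seed = 31L, deformation = d,
                                         false_object_rate = 4L))
    for (g in seq_along(s$components)) {
      cc <- s$components[[g]]
      expect_false(any(cc$lumen & cc$epithelium))
      expect_false(any(cc$lumen & cc$nuclei))
      expect_false(any(cc$epithelium & cc$nuclei))
      union <- cc$lumen | cc$epithelium | cc$nuclei
      expect_true(all(s$gland_label_mask[union] == g))
    }
    # false objects never intersect gland regions
    fo <- s$false_objects$nuclei_mask | s$false_objects$white_mask
    expect_false(any(fo & s$gland_label_mask > 0))
  }
})

test_that("boundary displacement amplitude is monotone in deformation", {
  amps <- vapply(c(0, 0.2, 0.5, 0.8, 1), function(d)
    mean(generate_phantom(phantom_config(seed = 77L,
                                         deformation = d))$displacement),
    numeric(1))
  expect_true(all(diff(amps) >= 0))
  expect_equal(amps[1], 0)
})

test_that("invalid configurations are rejected", {
  expect_error(phantom_config(lumen_fraction = 1.2), "lumen_fraction")
  expect_error(phantom_config(n_glands = -1), "n_glands")
  expect_error(generate_phantom(phantom_config(image_size = c(48, 48),
                                               n_glands = 6L, seed = 1L)),
               "cannot place glands")
})

test_that("cohorts are balanced, labelled and seed-derived", {
  cfgs <- list(normal = grade_config("normal"), well = grade_config("well"))
  co <- generate_cohort(cfgs, n_per_class = 2L, seed = 9L)
  expect_length(co, 4L)
  expect_equal(vapply(co, `[[`, "", "class_label"),
               c("normal", "normal", "well", "well"))
  co2 <- generate_cohort(cfgs, n_per_class = 2L, seed = 10L)
  for (i in 1:4) expect_false(identical(co[[i]]$image, co2[[i]]$image))
  expect_error(generate_cohort(list(normal = grade_config("normal"),
                                    well = NULL), 2L, 1L),
               "missing or invalid config")
  expect_error(generate_cohort(cfgs, 0L, 1L), "n_per_class")
})
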