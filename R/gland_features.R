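# Gland-level morphometric features and the per-image feature bundle.

#' Select the k largest and k smallest glands by area
#'
#' Glands are ranked by region area (ties broken by gland id, so the
#' selection is deterministic); the top `k` and bottom `k` are returned,
#' deduplicated when fewer than `2k` glands exist.
#'
#' @param result a `segmentation_result`.
#' @param k glands from each end (default 5).
#' @return integer vector of selected gland indices in descending area
#'   order.
#' @export
select_glands <- function(result, k = 5L) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  n <- length(result$glands)
  if (n == 0)
    stop(paste("zero glands segmented: apply the bundle padding policy",
               "(see extract_bundle)"), call. = FALSE)
  areas <- vapply(result$glands, function(g) sum(g$region_mask), 0)
  ord <- order(-areas, seq_len(n))   # descending area, ties by id
  sel <- unique(c(head(ord, k), rev(tail(ord, k))))
  sel[order(-areas[sel], sel)]
}

#' Morphometric feature vector of one gland
#'
#' Distances are measured centroid-to-centroid from the lumen centroid;
#' epithelial "cells" are the connected components of the epithelium mask,
#' nuclei the per-nucleus masks. Components requiring at least two objects
#' (standard deviations) are 0 with a flag when undersupplied. Morphology is
#' computed on the full region mask. All distance/area features are in pixel
#' units; no magnification correction is applied.
#'
#' @param gland a `gland`.
#' @return named numeric vector of length 19 (attribute `"flags"` lists any
#'   degenerate components): sd of epithelial / nuclear centroid distances to
#'   the lumen centroid, sd of epithelial / nuclear areas, component size
#'   ratios (lumen, epithelium, nuclei over the gland, plus the three
#'   pairwise ratios) and region morphology (area, compactness, convex area,
#'   eccentricity, Euler number, major/minor axis length, orientation,
#'   perimeter).
#' @export
gland_features <- function(gland) {
  stopifnot(inherits(gland, "gland"))
  if (!any(gland$lumen_mask))
    stop("gland invariant violation: empty lumen", call. = FALSE)
  flags <- character(0)
  cen <- gland$lumen_centroid

  comp_stats <- function(masks, what) {
    if (length(masks) < 2) {
      flags <<- c(flags, paste0("too_few_", what))
      return(c(sd_dist = 0, sd_area = 0))
    }
    cents <- t(vapply(masks, mask_centroid, numeric(2)))
    dists <- sqrt((cents[, 1] - cen[["x"]])^2 + (cents[, 2] - cen[["y"]])^2)
    areas <- vapply(masks, sum, 0)
    c(sd_dist = sd(dists), sd_area = sd(areas))
  }
  epi_lab <- EBImage::bwlabel(gland$epithelium_mask * 1)
  n_epi <- max(epi_lab)
  epi_masks <- lapply(seq_len(n_epi), function(id) epi_lab == id)
  epi <- comp_stats(epi_masks, "epithelial_components")
  nuc <- comp_stats(gland$nuclei_masks, "nuclei")

  a_lum <- sum(gland$lumen_mask)
  a_epi <- sum(gland$epithelium_mask)
  a_nuc <- sum(vapply(gland$nuclei_masks, sum, 0))
  a_reg <- max(sum(gland$region_mask), 1)
  rat <- function(num, den) num / max(den, 1)

  region <- gland$region_mask
  idx <- which(region, arr.ind = TRUE)
  fit <- moment_ellipse(x = idx[, 2], y = idx[, 1])
  ecc <- sqrt(max(0, 1 - (fit$b / fit$a)^2))
  ecc <- min(ecc, 1 - 1e-12)
  hull <- chull(idx[, 2], idx[, 1])
  hx <- idx[hull, 2]; hy <- idx[hull, 1]
  convex_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  convex_area <- max(convex_area, a_reg)  # pixel-center hull never below area
  # Euler number = components - holes (holes: complement components not
  # touching the border)
  comp_lab <- EBImage::bwlabel(region * 1)
  hole_lab <- EBImage::bwlabel((!region) * 1)
  border_ids <- unique(c(hole_lab[1, ], hole_lab[nrow(region), ],
                         hole_lab[, 1], hole_lab[, ncol(region)]))
  holes <- setdiff(seq_len(max(hole_lab)), border_ids)
  out <- c(sd_dist_epithelium_to_lumen = unname(epi["sd_dist"]),
           sd_dist_nuclei_to_lumen = unname(nuc["sd_dist"]),
           sd_area_epithelium = unname(epi["sd_area"]),
           sd_area_nuclei = unname(nuc["sd_area"]),
           ratio_lumen_gland = rat(a_lum, a_reg),
           ratio_epithelium_gland = rat(a_epi, a_reg),
           ratio_nuclei_gland = rat(a_nuc, a_reg),
           ratio_lumen_epithelium = rat(a_lum, a_epi),
           ratio_lumen_nuclei = rat(a_lum, a_nuc),
           ratio_epithelium_nuclei = rat(a_epi, a_nuc),
           area = a_reg,
           compactness = mask_compactness(region),
           convex_area = convex_area,
           eccentricity = ecc,
           euler_number = max(comp_lab) - length(holes),
           major_axis_length = 2 * fit$a,
           minor_axis_length = 2 * fit$b,
           orientation = fit$theta,
           perimeter = mask_perimeter(region))
  attr(out, "flags") <- flags
  out
}

#' Bundle configuration for per-image feature extraction
#'
#' @param sgld an [sgld_config()].
#' @param k_glands glands selected from each end of the area ranking.
#' @param patch_size,n_subsets,subset_size patch feature parameters
#'   (see [patch_features()]).
#' @param segmentation a [segmentation_params()].
#' @return list of class `bundle_config`.
#' @export
bundle_config <- function(sgld = sgld_config(), k_glands = 5L,
                          patch_size = 64L, n_subsets = 5L,
                          subset_size = NULL,
                          segmentation = segmentation_params()) {
  structure(list(sgld = sgld, k_glands = as.integer(k_glands),
                 patch_size = as.integer(patch_size),
                 n_subsets = as.integer(n_subsets),
                 subset_size = subset_size,
                 segmentation = segmentation),
            class = "bundle_config")
}

#' Extract the three-scale feature bundle of one image
#'
#' Computes whole-image texture features, per-gland morphometrics of the
#' `2k` selected glands (largest and smallest by area) concatenated in
#' descending area order, and patch-subset texture features. Images with
#' fewer than `2k` glands repeat existing glands in area order (flagged
#' `padded`); images with no glands pad the gland block with zeros (flagged
#' `no_glands`), so the bundle length is identical for every image under a
#' fixed configuration.
#'
#' @param image H x W x 3 array, values 0-255.
#' @param label optional class label carried on the bundle.
#' @param segmentation optional precomputed `segmentation_result`.
#' @param config a [bundle_config()].
#' @param seed seed for patch subset sampling (and segmentation when not
#'   precomputed).
#' @return object of class `feature_bundle`: `image_features` (11),
#'   `gland_features` (2k x 19 values, named), `patch_features`
#'   (n_subsets x 11 matrix), `label`, `flags`, `config_hash`.
#' @export
extract_bundle <- function(image, label = NA_character_, segmentation = NULL,
                           config = bundle_config(), seed = 1L) {
  flags <- character(0)
  imf <- image_features(image, config$sgld)
  if (is.null(segmentation)) {
    par <- config$segmentation
    par$seed <- seed
    segmentation <- segment_image(image, par)
  }
  k <- config$k_glands
  n_slots <- 2L * k
  gf_dim <- 19L
  gnames <- names(gland_features_template())
  if (length(segmentation$glands) == 0) {
    flags <- c(flags, "no_glands")
    gmat <- matrix(0, n_slots, gf_dim)
  } else {
    sel <- select_glands(segmentation, k)
    if (length(sel) < n_slots) flags <- c(flags, "padded")
    sel <- rep_len(sel, n_slots)
    gmat <- t(vapply(sel, function(i)
      as.numeric(gland_features(segmentation$glands[[i]])), numeric(gf_dim)))
  }
  gvec <- as.vector(t(gmat))
  names(gvec) <- paste0("gland", rep(seq_len(n_slots), each = gf_dim), "_",
                        rep(gnames, n_slots))
  pf <- patch_features(image, config$patch_size, config$n_subsets,
                       config$subset_size, seed = seed, config = config$sgld)
  structure(list(image_features = imf,
                 gland_features = gvec,
                 patch_features = pf,
                 label = label,
                 flags = flags,
                 config_hash = config_hash(unclass(config))),
            class = "feature_bundle")
}

gland_features_template <- function() {
  setNames(numeric(19),
           c("sd_dist_epithelium_to_lumen", "sd_dist_nuclei_to_lumen",
             "sd_area_epithelium", "sd_area_nuclei",
             "ratio_lumen_gland", "ratio_epithelium_gland",
             "ratio_nuclei_gland", "ratio_lumen_epithelium",
             "ratio_lumen_nuclei", "ratio_epithelium_nuclei",
             "area", "compactness", "convex_area", "eccentricity",
             "euler_number", "major_axis_length", "minor_axis_length",
             "orientation", "perimeter"))
}
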