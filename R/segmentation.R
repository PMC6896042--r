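# Multi-step gland segmentation: candidate discrimination, lumen detection,
# internal-region growth, boundary-nucleus attachment, gland finalisation.

#' Per-object cohort features for candidate discrimination
#'
#' For every candidate object: its area and compactness
#' (4*pi*area/perimeter^2), the mean distance to its `k_neighbors` nearest
#' cohort neighbours, and local tissue-composition ratios measured in a
#' context window around the object. The default window is a morphological
#' shell (pixels within `shell_width` of the object but not adjacent to it),
#' which is scale-free; `context = "cocentric"` instead uses the annulus
#' between the object's fitted ellipse and the next co-centric overlay
#' ellipse. The class ratio is purple-to-white/pink area for purple objects
#' and white-to-pink/purple for white objects, with an epsilon denominator
#' guard.
#'
#' @param objects list of `ellipse_object` (>= 2).
#' @param cmap the image's `cluster_map`.
#' @param k_neighbors neighbours used for the centre-distance feature.
#' @param scales co-centric ellipse scale factors (see
#'   [overlay_cocentric_ellipses()]).
#' @param eps denominator guard for area ratios, in pixels.
#' @param context `"shell"` (default) or `"cocentric"` window.
#' @param shell_width shell radius in pixels for the default window.
#' @return data.frame with one row per object (`area`, `compactness`,
#'   `nn_dist`, `white_ratio`, `pink_ratio`, `purple_ratio`, `class_ratio`);
#'   cohort-level summaries are attached as attribute `"cohort"` (n_objects,
#'   mean pairwise centre distance, mean/sd of area and compactness, mean
#'   class area ratio).
#' @export
cohort_features <- function(objects, cmap, k_neighbors = 5L,
                            scales = c(1, 1.5, 2, 2.5), eps = 1,
                            context = c("shell", "cocentric"),
                            shell_width = 6L) {
  context <- match.arg(context)
  if (length(objects) < 2)
    stop("insufficient objects: need at least 2 to compute cohort features",
         call. = FALSE)
  stopifnot(inherits(cmap, "cluster_map"))
  n <- length(objects)
  centers <- object_centers(objects)
  D <- as.matrix(dist(centers))
  diag(D) <- Inf
  k <- min(k_neighbors, n - 1L)
  nn_dist <- apply(D, 1, function(r) mean(sort(r)[seq_len(k)]))

  labs <- cmap$labels
  feats <- lapply(seq_len(n), function(i) {
    obj <- objects[[i]]
    if (context == "shell") {
      m <- object_mask(obj)
      ann <- dilate_mask(m, 2L * shell_width + 1L) & !dilate_mask(m, 3L)
    } else {
      ov <- overlay_cocentric_ellipses(obj, n = length(scales), scales = scales)
      # the innermost annulus: wider shells dilute the signal with stroma
      ann <- ov$masks[[min(2L, length(scales))]] & !ov$masks[[1]]
    }
    lv <- labs[ann]
    w <- sum(lv == 1L); p <- sum(lv == 2L); u <- sum(lv == 3L)
    cls <- if (obj$component_class == "PURPLE_CANDIDATE")
      u / max(w + p, eps) else w / max(p + u, eps)
    tot <- max(length(lv), 1)
    c(area = obj$area,
      compactness = mask_compactness(object_mask(obj)),
      nn_dist = unname(nn_dist[i]),
      white_ratio = w / tot, pink_ratio = p / tot, purple_ratio = u / tot,
      class_ratio = cls)
  })
  df <- as.data.frame(do.call(rbind, feats))
  Dfin <- D; Dfin[!is.finite(Dfin)] <- NA
  attr(df, "cohort") <- list(
    n_objects = n,
    mean_pairwise_center_distance = mean(Dfin, na.rm = TRUE),
    mean_area = mean(df$area), sd_area = sd(df$area),
    mean_compactness = mean(df$compactness),
    sd_compactness = sd(df$compactness),
    area_ratio = mean(df$class_ratio))
  df
}

#' Discriminate true glandular components from false positives
#'
#' Agglomerative hierarchical clustering (Ward linkage on z-scored features,
#' cut at 2 clusters) splits a candidate cohort into true components and
#' false positives. The TRUE cluster is chosen by stain context: purple
#' objects (nuclei) are true when their surroundings are rich in white
#' lumen/cytoplasm; white objects are true when ringed by purple nuclei.
#' A silhouette-based homogeneity guard (used by [segment_image()]) can
#' declare a cohort homogeneous, in which case every object is marked true.
#'
#' @param objects list of `ellipse_object` (all of one component class).
#' @param features their [cohort_features()] table.
#' @param min_silhouette homogeneity guard: if the mean silhouette of the
#'   2-cut is below this value the cohort is not split (default 0 = always
#'   split, the faithful 2-cut).
#' @param criterion_floor stain-context floor: a cluster is only flagged
#'   FALSE when its mean context ratio falls below this value (default 0 =
#'   off, the faithful unconditional 2-cut). False positives sit in stroma
#'   and have near-zero gland context, whereas true components always carry
#'   some; the floor prevents a homogeneous all-true cohort from being split
#'   by incidental shape variation. When both clusters fall below the floor
#'   the whole cohort is marked false.
#' @param feature_cols feature columns used for clustering.
#' @return `objects` with `is_true` set on each.
#' @export
discriminate_true_false <- function(objects, features, min_silhouette = 0,
                                    criterion_floor = 0,
                                    feature_cols = c("area", "compactness",
                                                     "nn_dist", "class_ratio",
                                                     "white_ratio")) {
  if (length(objects) < 2)
    stop("need at least 2 objects to discriminate", call. = FALSE)
  X <- as.matrix(features[, intersect(feature_cols, colnames(features)),
                          drop = FALSE])
  cl <- hclust_cut2(X)
  Xs <- zscore_drop_constant(X)
  if (min_silhouette > 0 && silhouette2(Xs, cl) < min_silhouette) {
    for (i in seq_along(objects)) objects[[i]]$is_true <- TRUE
    attr(objects, "homogeneous") <- TRUE
    return(objects)
  }
  purple <- objects[[1]]$component_class == "PURPLE_CANDIDATE"
  crit <- if (purple) features$white_ratio else features$purple_ratio
  m1 <- mean(crit[cl == 1]); m2 <- mean(crit[cl == 2])
  if (min(m1, m2) >= criterion_floor && criterion_floor > 0) {
    for (i in seq_along(objects)) objects[[i]]$is_true <- TRUE
    attr(objects, "homogeneous") <- TRUE
    return(objects)
  }
  true_cl <- if (m1 >= m2) 1L else 2L
  for (i in seq_along(objects)) {
    in_true <- (cl[i] == true_cl) && max(m1, m2) >= criterion_floor
    objects[[i]]$is_true <- in_true
  }
  attr(objects, "homogeneous") <- FALSE
  objects
}

#' Separate true white objects into lumina and cytoplasm fragments
#'
#' 2-cut hierarchical clustering on shape features (area, compactness,
#' neighbour distance). The cluster with the larger mean area is the LUMEN
#' class (lumina are the large central cavities; cytoplasm appears as small
#' fragments); exact ties break towards higher mean compactness. When the
#' cohort is homogeneous (silhouette guard), every object is a lumen —
#' on clean tissue all surviving white objects are glandular cavities.
#'
#' @param objects true white `ellipse_object`s (>= 2).
#' @param features their [cohort_features()] rows.
#' @param min_silhouette homogeneity guard threshold (0 = always split).
#' @param min_area_ratio scale guard: the split is only accepted when the
#'   clusters' mean areas differ by at least this factor (default 1 = off);
#'   lumina legitimately vary 2-3x in area while cytoplasm fragments are an
#'   order of magnitude smaller, so near-equal clusters indicate a
#'   homogeneous all-lumen cohort.
#' @return character vector over objects: `"LUMEN"` or `"CYTOPLASM"`.
#' @export
detect_lumina <- function(objects, features, min_silhouette = 0,
                          min_area_ratio = 1) {
  if (length(objects) < 2)
    stop("need at least 2 white objects for lumen detection", call. = FALSE)
  X <- as.matrix(features[, c("area", "compactness", "nn_dist")])
  cl <- hclust_cut2(X)
  Xs <- zscore_drop_constant(X)
  m1 <- mean(features$area[cl == 1]); m2 <- mean(features$area[cl == 2])
  if ((min_silhouette > 0 && silhouette2(Xs, cl) < min_silhouette) ||
      max(m1, m2) < min_area_ratio * max(min(m1, m2), 1))
    return(rep("LUMEN", length(objects)))
  a1 <- mean(features$area[cl == 1]); a2 <- mean(features$area[cl == 2])
  if (a1 == a2) {  # deterministic tie-break by compactness
    c1 <- mean(features$compactness[cl == 1])
    c2 <- mean(features$compactness[cl == 2])
    lum_cl <- if (c1 >= c2) 1L else 2L
  } else lum_cl <- if (a1 > a2) 1L else 2L
  ifelse(cl == lum_cl, "LUMEN", "CYTOPLASM")
}

#' Grow the internal gland region by iterative dilation
#'
#' The union of lumen and epithelial cytoplasm is dilated with a size-3 disk
#' until the first iteration that adds no new nucleus pixels. Iterations that
#' add no nuclei are tolerated only before any nucleus has been reached (the
#' region must first grow across the gap to the nucleus ring); once contact
#' is made, the first non-adding iteration stops the growth, so one further
#' manual dilation is guaranteed to add no nucleus pixels. When the image
#' contains no nuclei at all, a single dilation round is attempted and the
#' input is returned.
#'
#' @param lumen_mask logical matrix (non-empty).
#' @param cytoplasm_mask optional logical matrix unioned with the lumen.
#' @param nuclei_mask logical matrix of nucleus pixels.
#' @param brush_size dilation structuring element size (default 3 = 3x3 disk).
#' @param support optional logical matrix restricting growth (e.g. the
#'   non-stroma pixels); the region never grows outside it.
#' @return logical matrix, a superset of the input union.
#' @export
grow_internal_region <- function(lumen_mask, cytoplasm_mask = NULL,
                                 nuclei_mask, brush_size = 3L,
                                 support = NULL) {
  if (!any(lumen_mask)) stop("lumen mask is empty", call. = FALSE)
  region <- lumen_mask
  if (!is.null(cytoplasm_mask)) region <- region | cytoplasm_mask
  if (!is.null(support)) support <- support | region | nuclei_mask
  nuclei_exist <- any(nuclei_mask)
  reached <- any(region & nuclei_mask)
  n_in <- sum(region & nuclei_mask)
  max_iter <- sum(dim(region))
  for (it in seq_len(max_iter)) {
    cand <- dilate_mask(region, brush_size)
    if (!is.null(support)) cand <- cand & support
    cand <- cand | region
    if (identical(cand, region)) break      # nothing reachable any more
    new_in <- sum(cand & nuclei_mask)
    if (new_in > n_in) {
      region <- cand; n_in <- new_in; reached <- TRUE
    } else {
      if (reached || !nuclei_exist) break   # fixed point w.r.t. nuclei
      region <- cand                        # still travelling towards ring
    }
  }
  region
}

#' Select candidate boundary nuclei by radial ray casting
#'
#' From the lumen centroid a ray is cast through every boundary pixel of the
#' internal region and extended to the image border; on each ray the first
#' nucleus intersected (closest to the lumen) becomes a candidate. A nucleus
#' hit by at least one ray is selected once.
#'
#' @param internal_region logical matrix containing the lumen centroid.
#' @param lumen_centroid (x, y) in pixels.
#' @param nuclei list of true-nucleus `ellipse_object`s.
#' @param step ray sampling step in pixels.
#' @return subset of `nuclei` selected as candidate boundary nuclei.
#' @export
select_boundary_nuclei <- function(internal_region, lumen_centroid, nuclei,
                                   step = 0.5) {
  H <- nrow(internal_region); W <- ncol(internal_region)
  cx <- lumen_centroid[[1]]; cy <- lumen_centroid[[2]]
  ri <- round(cy); ci <- round(cx)
  if (ri < 1 || ri > H || ci < 1 || ci > W || !internal_region[ri, ci])
    stop("lumen centroid lies outside the internal region", call. = FALSE)
  if (length(nuclei) == 0) return(list())

  idmap <- matrix(0L, H, W)
  for (i in seq_along(nuclei)) idmap[nuclei[[i]]$pixels] <- i

  bnd <- which(mask_boundary(internal_region), arr.ind = TRUE)
  if (nrow(bnd) == 0) return(list())
  dx <- bnd[, 2] - cx; dy <- bnd[, 1] - cy
  nrm <- sqrt(dx^2 + dy^2)
  keep <- nrm > 1e-9
  dx <- dx[keep] / nrm[keep]; dy <- dy[keep] / nrm[keep]
  if (length(dx) == 0) return(list())

  tmax <- sqrt(H^2 + W^2)
  tseq <- seq(step, tmax, by = step)
  hit <- logical(length(nuclei))
  # vectorised over rays in blocks to bound memory
  block <- 256L
  for (s in seq(1, length(dx), by = block)) {
    e <- min(s + block - 1L, length(dx))
    xs <- outer(dx[s:e], tseq) + cx
    ys <- outer(dy[s:e], tseq) + cy
    rr <- round(ys); cc <- round(xs)
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    ids <- matrix(0L, nrow(rr), ncol(rr))
    ids[ok] <- idmap[cbind(rr[ok], cc[ok])]
    has <- (ids > 0L) + 0
    first <- max.col(has, ties.method = "first")
    rows_hit <- which(rowSums(has) > 0)
    if (length(rows_hit))
      hit[unique(ids[cbind(rows_hit, first[rows_hit])])] <- TRUE
  }
  nuclei[hit]
}

#' Remove false boundary nuclei by neighbour-distance clustering
#'
#' Each candidate is described by its sorted distances to its `k` nearest
#' candidate neighbours; a Ward 2-cut separates regularly spaced ring nuclei
#' from outliers, and the cluster with the smaller mean neighbour distance is
#' kept. Two homogeneity guards treat the cohort as a clean ring and remove
#' nothing: a mean 2-cut silhouette below `min_silhouette`, or a relative
#' spread of mean neighbour distances below `min_rel_spread` (z-scoring a
#' near-constant feature would otherwise amplify rasterisation noise into a
#' spurious split). With fewer than `k + 2` candidates the set is passed
#' through unchanged with a warning.
#'
#' @param candidates list of candidate nucleus `ellipse_object`s.
#' @param k number of neighbours (default 5).
#' @param min_silhouette homogeneity guard threshold (default 0.35).
#' @param min_rel_spread raw-scale guard: minimum
#'   `(max - min) / mean` of the per-nucleus mean neighbour distance for a
#'   split to be considered (default 0.25).
#' @return the retained nuclei (attribute `"removed"` carries the rest).
#' @export
remove_false_nuclei <- function(candidates, k = 5L, min_silhouette = 0.35,
                                min_rel_spread = 0.25) {
  n <- length(candidates)
  if (n < k + 2L) {
    warning(sprintf(
      "only %d candidate nuclei (< %d); passing through unchanged", n, k + 2L))
    attr(candidates, "removed") <- list()
    return(candidates)
  }
  centers <- object_centers(candidates)
  D <- as.matrix(dist(centers)); diag(D) <- Inf
  X <- t(apply(D, 1, function(r) sort(r)[seq_len(k)]))
  colnames(X) <- paste0("nn", seq_len(k))
  mean_nd_all <- rowMeans(X)
  if ((max(mean_nd_all) - min(mean_nd_all)) / mean(mean_nd_all) <
      min_rel_spread) {
    attr(candidates, "removed") <- list()
    return(candidates)
  }
  cl <- tryCatch(hclust_cut2(X), error = function(e) NULL)
  if (is.null(cl)) {  # perfectly regular ring: nothing to remove
    attr(candidates, "removed") <- list()
    return(candidates)
  }
  Xs <- zscore_drop_constant(X)
  if (silhouette2(Xs, cl) < min_silhouette) {
    attr(candidates, "removed") <- list()
    return(candidates)
  }
  mean_nd <- rowMeans(X)
  keep_cl <- if (mean(mean_nd[cl == 1]) <= mean(mean_nd[cl == 2])) 1L else 2L
  kept <- candidates[cl == keep_cl]
  attr(kept, "removed") <- candidates[cl != keep_cl]
  kept
}

#' Finalise a gland by dilating the internal region over its boundary nuclei
#'
#' The internal region is dilated (size-3 disk) until every pixel of every
#' boundary nucleus is inside, constituting the complete gland region. If the
#' nuclei are already covered no dilation happens.
#'
#' @param internal_region logical matrix.
#' @param boundary_nuclei list of nucleus `ellipse_object`s (may be empty, in
#'   which case the gland is the internal region, flagged).
#' @param lumen_mask logical matrix of the gland's lumen object.
#' @param brush_size dilation structuring element size.
#' @param support optional growth restriction mask (nucleus pixels are always
#'   allowed).
#' @return object of class `gland`: `lumen_mask`, `epithelium_mask`,
#'   `nuclei_masks` (list of logical matrices), `region_mask`,
#'   `lumen_centroid`, `flags`.
#' @export
finalize_gland <- function(internal_region, boundary_nuclei, lumen_mask,
                           brush_size = 3L, support = NULL) {
  region <- internal_region
  target <- matrix(FALSE, nrow(region), ncol(region))
  for (nucl in boundary_nuclei) target[nucl$pixels] <- TRUE
  if (!is.null(support)) support <- support | region | target
  max_iter <- sum(dim(region))
  it <- 0L
  while (any(target & !region) && it < max_iter) {
    it <- it + 1L
    cand <- dilate_mask(region, brush_size)
    if (!is.null(support)) cand <- cand & support
    cand <- cand | region
    if (identical(cand, region)) { region <- region | target; break }
    region <- cand
  }
  nuclei_masks <- lapply(boundary_nuclei, object_mask)
  nuc_union <- Reduce(`|`, nuclei_masks, target & FALSE) | target
  lum <- lumen_mask & region & !nuc_union
  epi <- region & !lum & !nuc_union
  flags <- character(0)
  if (length(boundary_nuclei) == 0) flags <- c(flags, "no_boundary_nuclei")
  structure(list(lumen_mask = lum,
                 epithelium_mask = epi,
                 nuclei_masks = lapply(nuclei_masks, function(m) m & region),
                 region_mask = region,
                 lumen_centroid = mask_centroid(lum),
                 flags = flags,
                 dilation_iterations = it),
            class = "gland")
}

#' Parameters of the gland segmentation pipeline
#'
#' @param seed clustering seed.
#' @param erosion_radius disk radius for cluster cleanup erosion.
#' @param min_area minimum candidate component area in pixels (purple
#'   nuclei candidates).
#' @param min_area_white minimum white candidate area in pixels: lumina and
#'   cytoplasm fragments are larger than single nuclei, so white specks are
#'   dropped earlier.
#' @param k_neighbors neighbours for the centre-distance feature.
#' @param cocentric_scales co-centric overlay ellipse scales.
#' @param min_silhouette homogeneity guard used in the discrimination,
#'   lumen-detection and false-nucleus steps.
#' @param criterion_floor stain-context floor for
#'   [discriminate_true_false()].
#' @param min_area_ratio area-scale guard for [detect_lumina()].
#' @param brush_size dilation structuring element size.
#' @param contrast_stretch apply [enhance_contrast()] first.
#' @param restrict_to_tissue constrain region growth to non-stroma pixels.
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(seed = 1L, erosion_radius = 1L, min_area = 15L,
                                min_area_white = 60L,
                                k_neighbors = 5L,
                                cocentric_scales = c(1, 1.5, 2, 2.5),
                                min_silhouette = 0.35,
                                criterion_floor = 0.1,
                                min_area_ratio = 4,
                                brush_size = 3L,
                                contrast_stretch = TRUE,
                                restrict_to_tissue = TRUE) {
  structure(as.list(environment()), class = "segmentation_params")
}

#' Segment all glands in an H&E image
#'
#' Runs the full chain: contrast stretch, K-means tissue clustering, cluster
#' erosion, ellipse fitting of white and purple candidates, true/false
#' discrimination, lumen detection, per-lumen internal-region growth,
#' radial-line boundary-nucleus selection, false-nucleus removal and gland
#' finalisation. Pixels contested between glands go to the nearest lumen
#' centroid. Finding no lumina yields an empty result with a diagnostic, not
#' an error.
#'
#' @param image H x W x 3 array, values 0-255.
#' @param params a [segmentation_params()].
#' @return object of class `segmentation_result`: `glands` (list of `gland`,
#'   labelled in row-major order of their lumen centroids),
#'   `gland_label_mask` (integer matrix, 0 = background), `cluster_map`,
#'   `diagnostics` (character vector).
#' @export
segment_image <- function(image, params = segmentation_params()) {
  assert_rgb_image(image)
  diagnostics <- character(0)
  img <- if (params$contrast_stretch) enhance_contrast(image) else image
  cmap <- cluster_tissue(img, seed = params$seed)
  masks <- erode_clusters(cmap, params$erosion_radius)
  support <- if (params$restrict_to_tissue) cmap$labels != 2L else NULL

  purple <- fit_ellipses(masks$purple, "PURPLE_CANDIDATE", params$min_area)
  white <- fit_ellipses(masks$white, "WHITE_CANDIDATE", params$min_area_white)

  classify_true <- function(objs) {
    if (length(objs) < 2) {
      for (i in seq_along(objs)) objs[[i]]$is_true <- TRUE
      return(objs)
    }
    fe <- cohort_features(objs, cmap, params$k_neighbors,
                          params$cocentric_scales)
    tryCatch(
      discriminate_true_false(objs, fe,
                              min_silhouette = params$min_silhouette,
                              criterion_floor = params$criterion_floor),
      error = function(e) {
        for (i in seq_along(objs)) objs[[i]]$is_true <- TRUE
        objs
      })
  }
  purple <- classify_true(purple)
  white <- classify_true(white)
  true_nuclei <- purple[vapply(purple, `[[`, TRUE, "is_true")]
  true_white <- white[vapply(white, `[[`, TRUE, "is_true")]

  empty_result <- function(msg) {
    structure(list(glands = list(),
                   gland_label_mask = matrix(0L, dim(image)[1], dim(image)[2]),
                   cluster_map = cmap,
                   diagnostics = c(diagnostics, msg)),
              class = "segmentation_result")
  }
  if (length(true_white) == 0) return(empty_result("no lumina: no white objects"))

  if (length(true_white) == 1) {
    kinds <- "LUMEN"
  } else {
    fw <- cohort_features(true_white, cmap, params$k_neighbors,
                          params$cocentric_scales)
    kinds <- tryCatch(
      detect_lumina(true_white, fw, min_silhouette = params$min_silhouette,
                    min_area_ratio = params$min_area_ratio),
      error = function(e) rep("LUMEN", length(true_white)))
  }
  lumina <- true_white[kinds == "LUMEN"]
  if (length(lumina) == 0) return(empty_result("no lumina"))

  nuclei_mask <- matrix(FALSE, dim(image)[1], dim(image)[2])
  for (nucl in true_nuclei) nuclei_mask[nucl$pixels] <- TRUE

  glands <- list()
  for (lum in lumina) {
    lmask <- object_mask(lum)
    internal <- grow_internal_region(lmask, NULL, nuclei_mask,
                                     params$brush_size, support = support)
    cand <- tryCatch(
      select_boundary_nuclei(internal, lum$center, true_nuclei),
      error = function(e) list())
    kept <- if (length(cand))
      suppressWarnings(remove_false_nuclei(cand, min_silhouette =
                                             params$min_silhouette))
    else list()
    gl <- finalize_gland(internal, kept, lmask, params$brush_size,
                         support = support)
    glands[[length(glands) + 1L]] <- gl
  }

  # merge near-duplicate glands: two lumina whose grown regions largely
  # coincide sit in the same tissue component (e.g. a fragmented cavity),
  # and splitting that component in half would be artefactual; genuinely
  # distinct glands overlap at most marginally
  if (length(glands) > 1) {
    repeat {
      merged <- FALSE
      for (i in seq_along(glands)) {
        for (j in seq_along(glands)) {
          if (j <= i) next
          ri <- glands[[i]]$region_mask; rj <- glands[[j]]$region_mask
          inter <- sum(ri & rj)
          if (inter == 0) next
          iou <- inter / sum(ri | rj)
          if (iou >= 0.5) {
            big <- if (sum(glands[[i]]$lumen_mask) >=
                       sum(glands[[j]]$lumen_mask)) i else j
            gm <- glands[[big]]
            gm$region_mask <- ri | rj
            nuc <- c(glands[[i]]$nuclei_masks, glands[[j]]$nuclei_masks)
            keys <- vapply(nuc, function(m) {
              w <- which(m); paste(length(w), w[1], w[length(w)])
            }, "")
            gm$nuclei_masks <- nuc[!duplicated(keys)]
            nuc_union <- Reduce(`|`, gm$nuclei_masks, gm$region_mask & FALSE)
            gm$lumen_mask <- glands[[big]]$lumen_mask & !nuc_union
            gm$epithelium_mask <- gm$region_mask & !gm$lumen_mask & !nuc_union
            gm$lumen_centroid <- mask_centroid(gm$lumen_mask)
            glands[[min(i, j)]] <- gm
            glands[[max(i, j)]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged || length(glands) < 2) break
    }
  }

  # order glands row-major by lumen centroid; resolve contested pixels by
  # nearest lumen centroid
  cys <- vapply(glands, function(g) g$lumen_centroid[["y"]], 0)
  cxs <- vapply(glands, function(g) g$lumen_centroid[["x"]], 0)
  glands <- glands[order(cys, cxs)]
  H <- dim(image)[1]; W <- dim(image)[2]
  label <- matrix(0L, H, W)
  bestd <- matrix(Inf, H, W)
  col_idx <- matrix(rep(seq_len(W), each = H), H, W)
  row_idx <- matrix(rep(seq_len(H), W), H, W)
  for (g in seq_along(glands)) {
    gl <- glands[[g]]
    m <- gl$region_mask
    dcent <- (col_idx - gl$lumen_centroid[["x"]])^2 +
      (row_idx - gl$lumen_centroid[["y"]])^2
    take <- m & (dcent < bestd)
    label[take] <- g
    bestd[take] <- dcent[take]
  }
  for (g in seq_along(glands)) {   # trim masks to the resolved territory
    own <- label == g
    glands[[g]]$region_mask <- glands[[g]]$region_mask & own
    glands[[g]]$lumen_mask <- glands[[g]]$lumen_mask & own
    glands[[g]]$epithelium_mask <- glands[[g]]$epithelium_mask & own
    glands[[g]]$nuclei_masks <-
      lapply(glands[[g]]$nuclei_masks, function(m) m & own)
    glands[[g]]$nuclei_masks <-
      glands[[g]]$nuclei_masks[vapply(glands[[g]]$nuclei_masks, any, TRUE)]
  }
  structure(list(glands = glands, gland_label_mask = label,
                 cluster_map = cmap, diagnostics = diagnostics),
            class = "segmentation_result")
}
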