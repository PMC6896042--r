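#' Linear contrast stretch of an RGB image
#'
#' Stretches each channel so the chosen quantile range spans `[0, 255]`.
#' With the default bounds (minimum/maximum) the operation is exactly
#' idempotent; a constant channel is left unchanged.
#'
#' @param image H x W x 3 array with values in 0-255.
#' @param lower,upper quantile bounds of the stretch (defaults 0 and 1,
#'   i.e. a min-max stretch; a robust percentile stretch is obtained with
#'   e.g. `lower = 0.01, upper = 0.99`).
#' @return image array of the same shape, values in `[0, 255]`.
#' @export
enhance_contrast <- function(image, lower = 0, upper = 1) {
  assert_rgb_image(image)
  stopifnot(lower < upper)
  out <- image
  for (ch in 1:3) {
    v <- image[, , ch]
    lo <- quantile(v, lower, names = FALSE)
    hi <- quantile(v, upper, names = FALSE)
    if (hi > lo) out[, , ch] <- clamp((v - lo) / (hi - lo) * 255, 0, 255)
  }
  out
}

#' Convert an RGB image to a quantized grayscale raster
#'
#' Luminance (0.299 R + 0.587 G + 0.114 B) quantized into `levels` equal-width
#' bins of the full 8-bit range, so the mapping is monotone in luminance and
#' independent of image content: pure black maps to 0, pure white to
#' `levels - 1`.
#'
#' @param image H x W x 3 array, values 0-255.
#' @param levels number of gray levels (>= 2); 8 matches the texture
#'   pipeline's 8 x 8 co-occurrence matrices.
#' @return integer matrix with values in `0 .. levels - 1`.
#' @export
to_grayscale <- function(image, levels = 8L) {
  assert_rgb_image(image)
  if (levels < 2) stop("levels must be >= 2", call. = FALSE)
  lum <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  q <- pmin(floor(lum / 256 * levels), levels - 1)
  storage.mode(q) <- "integer"
  q
}

.tissue_levels <- c("WHITE", "PINK", "PURPLE")

#' Partition pixels into white, pink and purple tissue clusters
#'
#' K-means (k = 3, k-means++-style multiple restarts) on raw RGB pixel
#' vectors. Semantic names are assigned from the cluster centroids by stain
#' logic rather than cluster index, so the labelling is invariant to K-means
#' ordering: the most luminous centroid is WHITE (lumen/cytoplasm), the
#' darkest is PURPLE (hematoxylin-stained nuclei), the remaining one PINK
#' (eosin-stained stroma).
#'
#' @param image H x W x 3 array, values 0-255.
#' @param seed integer; makes the clustering deterministic.
#' @param nstart number of K-means restarts.
#' @return object of class `cluster_map`: list with `labels` (integer matrix,
#'   1 = WHITE, 2 = PINK, 3 = PURPLE), and `centers` (3 x 3 matrix of RGB
#'   centroids with semantic rownames).
#' @export
cluster_tissue <- function(image, seed = 1L, nstart = 10L) {
  assert_rgb_image(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  X <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
             as.vector(image[, , 3]))
  if (nrow(unique(X)) < 3)
    stop("degenerate clustering: fewer than 3 distinct colors", call. = FALSE)
  km <- with_seed(seed,
                  suppressWarnings(kmeans(X, centers = 3, nstart = nstart,
                                          iter.max = 50)))
  lum <- km$centers %*% c(0.299, 0.587, 0.114)
  sem <- integer(3)               # kmeans index -> semantic code
  sem[which.max(lum)] <- 1L       # WHITE
  sem[which.min(lum)] <- 3L       # PURPLE
  sem[sem == 0L] <- 2L            # PINK
  labels <- matrix(sem[km$cluster], H, W)
  centers <- km$centers[order(sem), , drop = FALSE]
  dimnames(centers) <- list(.tissue_levels, c("R", "G", "B"))
  structure(list(labels = labels, centers = centers), class = "cluster_map")
}

#' Per-cluster binary masks of a cluster map
#' @param cmap a `cluster_map`.
#' @return named list of logical matrices (`white`, `pink`, `purple`).
#' @export
cluster_masks <- function(cmap) {
  stopifnot(inherits(cmap, "cluster_map"))
  list(white = cmap$labels == 1L,
       pink = cmap$labels == 2L,
       purple = cmap$labels == 3L)
}

#' Morphological erosion of the tissue cluster masks
#'
#' Each of the three binary cluster masks is eroded independently with a
#' disk structuring element; radius 0 is the identity.
#'
#' @param cmap a `cluster_map` (or a named list of logical masks).
#' @param radius disk radius in pixels (>= 0; default 1).
#' @return named list of eroded logical masks (`white`, `pink`, `purple`).
#' @export
erode_clusters <- function(cmap, radius = 1L) {
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  masks <- if (inherits(cmap, "cluster_map")) cluster_masks(cmap) else cmap
  if (radius == 0) return(masks)
  lapply(masks, erode_mask, radius = radius)
}
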