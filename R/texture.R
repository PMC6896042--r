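# Spatial gray-level dependence (co-occurrence) matrices and Haralick
# texture features.

#' SGLD configuration
#'
#' @param d pixel offset (>= 1; default 1).
#' @param angles subset of c(0, 45, 90, 135) degrees.
#' @param gray_levels number of gray levels G (>= 2; default 8, giving the
#'   8 x 8 matrices of the texture pipeline).
#' @param symmetric symmetrise the matrix (count each pair in both orders).
#' @param normalize divide by the total count so entries sum to 1.
#' @return list of class `sgld_config`.
#' @export
sgld_config <- function(d = 1L, angles = c(0, 45, 90, 135), gray_levels = 8L,
                        symmetric = TRUE, normalize = TRUE) {
  if (d < 1) stop("offset d must be >= 1", call. = FALSE)
  if (gray_levels < 2) stop("gray_levels must be >= 2", call. = FALSE)
  if (!all(angles %in% c(0, 45, 90, 135)))
    stop("angles must be a subset of {0, 45, 90, 135}", call. = FALSE)
  structure(list(d = as.integer(d), angles = angles,
                 gray_levels = as.integer(gray_levels),
                 symmetric = symmetric, normalize = normalize),
            class = "sgld_config")
}

# displacement (drow, dcol) for angle theta at offset d; y grows downward,
# angles measured counter-clockwise as in the usual co-occurrence convention
sgld_offset <- function(angle, d) {
  switch(as.character(angle),
         "0" = c(0L, d),
         "45" = c(-d, d),
         "90" = c(-d, 0L),
         "135" = c(-d, -d),
         stop("unsupported angle", call. = FALSE))
}

#' Co-occurrence counts of gray-level pairs at one displacement
#'
#' Counts pairs of gray levels separated by offset `d` at the given angle,
#' optionally symmetrised and normalised to a probability matrix.
#'
#' @param gray integer matrix with values in `0 .. G-1`.
#' @param config an [sgld_config()].
#' @param angle one of the configured angles (degrees).
#' @return object of class `sgld_matrix`: G x G matrix with the config
#'   attached as attribute `"config"`.
#' @export
compute_sgld <- function(gray, config = sgld_config(), angle = 0) {
  G <- config$gray_levels
  if (any(gray < 0) || any(gray >= G))
    stop("gray values must lie in 0 .. G-1", call. = FALSE)
  off <- sgld_offset(angle, config$d)
  H <- nrow(gray); W <- ncol(gray)
  r0 <- max(1, 1 - off[1]); r1 <- min(H, H - off[1])
  c0 <- max(1, 1 - off[2]); c1 <- min(W, W - off[2])
  if (r0 > r1 || c0 > c1)
    stop("no valid pairs: raster smaller than the displacement", call. = FALSE)
  A <- gray[r0:r1, c0:c1, drop = FALSE]
  B <- gray[(r0 + off[1]):(r1 + off[1]), (c0 + off[2]):(c1 + off[2]),
            drop = FALSE]
  counts <- matrix(tabulate(as.vector(A) * G + as.vector(B) + 1L, nbins = G * G),
                   G, G, byrow = TRUE)
  m <- sgld_accumulate(counts, config)
  attr(m, "config") <- config
  class(m) <- c("sgld_matrix", class(m))
  m
}

# symmetrise/normalise raw counts per config
sgld_accumulate <- function(counts, config) {
  m <- counts
  if (config$symmetric) m <- m + t(m)
  if (config$normalize) {
    tot <- sum(m)
    if (tot > 0) m <- m / tot
  }
  m
}

#' The 11 Haralick texture features of one or more SGLD matrices
#'
#' Computes entropy, energy, correlation, inverse difference moment, inertia
#' (contrast), sum average, sum entropy, sum variance, difference variance,
#' difference average and difference entropy per normalised matrix, then
#' averages across matrices (one per angle). Entropies use the natural
#' logarithm; gray levels are indexed from 0, so the sum index runs over
#' `0 .. 2(G-1)` and the difference index over `0 .. G-1`. For a constant
#' image the correlation is defined as 0 (both marginal variances vanish).
#'
#' @param matrices a single `sgld_matrix` or a list of them (all normalised,
#'   same G).
#' @return named numeric vector of length 11.
#' @export
haralick_features <- function(matrices) {
  if (inherits(matrices, "sgld_matrix")) matrices <- list(matrices)
  if (length(matrices) < 1) stop("need at least one matrix", call. = FALSE)
  G <- nrow(matrices[[1]])
  for (m in matrices) {
    if (nrow(m) != G || ncol(m) != G)
      stop("all matrices must share the same G", call. = FALSE)
    if (abs(sum(m) - 1) > 1e-8)
      stop("matrices must be normalized (entries summing to 1)", call. = FALSE)
  }
  feats <- vapply(matrices, haralick_one, numeric(11))
  rowMeans(feats)
}

haralick_one <- function(p) {
  G <- nrow(p)
  i <- matrix(rep(0:(G - 1), G), G, G)          # row index (first level)
  j <- t(i)                                      # column index (second level)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum((0:(G - 1)) * px); muy <- sum((0:(G - 1)) * py)
  sdx <- sqrt(sum(((0:(G - 1)) - mux)^2 * px))
  sdy <- sqrt(sum(((0:(G - 1)) - muy)^2 * py))
  ent <- function(v) { v <- v[v > 0]; -sum(v * log(v)) }

  # p_{x+y}(k), k = 0 .. 2(G-1) and p_{x-y}(k), k = 0 .. G-1
  ks <- 0:(2 * (G - 1))
  pxy_sum <- vapply(ks, function(k) sum(p[i + j == k]), numeric(1))
  kd <- 0:(G - 1)
  pxy_diff <- vapply(kd, function(k) sum(p[abs(i - j) == k]), numeric(1))

  sum_avg <- sum(ks * pxy_sum)
  diff_avg <- sum(kd * pxy_diff)
  corr <- if (sdx * sdy > 1e-12) (sum(i * j * p) - mux * muy) / (sdx * sdy) else 0

  c(entropy = ent(p),
    energy = sum(p^2),
    correlation = corr,
    inverse_difference_moment = sum(p / (1 + (i - j)^2)),
    inertia = sum((i - j)^2 * p),
    sum_average = sum_avg,
    sum_entropy = ent(pxy_sum),
    sum_variance = sum((ks - sum_avg)^2 * pxy_sum),
    difference_variance = sum((kd - diff_avg)^2 * pxy_diff),
    difference_average = diff_avg,
    difference_entropy = ent(pxy_diff))
}

#' Whole-image Haralick texture features
#'
#' Converts the image to a `G`-level grayscale raster, computes the SGLD
#' matrix at each configured angle and returns the angle-averaged 11
#' Haralick features. With the symmetric default angle set the features are
#' invariant to 90-degree image rotation. Quantization uses the absolute
#' 8-bit scale by default: a per-image contrast stretch would make the gray
#' bins image-dependent and confound texture comparison across images, so
#' the stretch is off here (it remains available for artifact-ridden
#' acquisitions).
#'
#' @param image H x W x 3 array, values 0-255.
#' @param config an [sgld_config()].
#' @param contrast_stretch apply [enhance_contrast()] first (default FALSE).
#' @return named numeric vector of length 11.
#' @export
image_features <- function(image, config = sgld_config(),
                           contrast_stretch = FALSE) {
  img <- if (contrast_stretch) enhance_contrast(image) else image
  gray <- to_grayscale(img, config$gray_levels)
  mats <- lapply(config$angles, function(a) compute_sgld(gray, config, a))
  haralick_features(mats)
}

#' Patch-subset texture features
#'
#' Tiles the image into non-overlapping `patch_size` squares (partial border
#' patches dropped), draws `n_subsets` random patch subsets (each of
#' `subset_size` patches, sampled without replacement given `seed`), pools
#' the raw SGLD counts of each subset's patches per angle, and computes the
#' angle-averaged Haralick features per subset.
#'
#' @param image H x W x 3 array, values 0-255.
#' @param patch_size patch side length in pixels (default 64).
#' @param n_subsets number of random subsets (default 5).
#' @param subset_size patches per subset (default: half the tiles).
#' @param seed integer controlling subset sampling.
#' @param config an [sgld_config()].
#' @param contrast_stretch apply [enhance_contrast()] to the whole image
#'   first (default FALSE, matching [image_features()]).
#' @return matrix `n_subsets` x 11 of texture features; tile count in
#'   attribute `"n_tiles"`, subsets in attribute `"subsets"`.
#' @export
patch_features <- function(image, patch_size = 64L, n_subsets = 5L,
                           subset_size = NULL, seed = 1L,
                           config = sgld_config(), contrast_stretch = FALSE) {
  assert_rgb_image(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (patch_size > min(H, W))
    stop("image smaller than one patch", call. = FALSE)
  img <- if (contrast_stretch) enhance_contrast(image) else image
  gray <- to_grayscale(img, config$gray_levels)
  nr <- H %/% patch_size; nc <- W %/% patch_size
  n_tiles <- nr * nc
  if (is.null(subset_size)) subset_size <- max(1L, n_tiles %/% 2L)
  if (subset_size < 1 || subset_size > n_tiles)
    stop("subset_size must lie in 1 .. number of tiles", call. = FALSE)

  raw_cfg <- config; raw_cfg$symmetric <- FALSE; raw_cfg$normalize <- FALSE
  tile_counts <- vector("list", n_tiles)
  t <- 0L
  for (ir in seq_len(nr)) for (ic in seq_len(nc)) {
    t <- t + 1L
    tile <- gray[((ir - 1) * patch_size + 1):(ir * patch_size),
                 ((ic - 1) * patch_size + 1):(ic * patch_size)]
    tile_counts[[t]] <- lapply(config$angles,
                               function(a) compute_sgld(tile, raw_cfg, a))
  }
  subsets <- with_seed(seed, lapply(seq_len(n_subsets),
                                    function(s) sort(sample.int(n_tiles, subset_size))))
  out <- matrix(NA_real_, n_subsets, 11)
  for (s in seq_len(n_subsets)) {
    mats <- lapply(seq_along(config$angles), function(ai) {
      pooled <- Reduce(`+`, lapply(subsets[[s]],
                                   function(t) unclass(tile_counts[[t]][[ai]])))
      m <- sgld_accumulate(pooled, config)
      class(m) <- c("sgld_matrix", class(m))
      m
    })
    out[s, ] <- haralick_features(mats)
  }
  colnames(out) <- names(haralick_one(diag(1, config$gray_levels) /
                                        config$gray_levels))
  attr(out, "n_tiles") <- n_tiles
  attr(out, "subsets") <- subsets
  out
}
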