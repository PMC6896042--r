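# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Run an expression with a fixed RNG state
#' @noRd
with_seed <- function(seed, expr) withr::with_seed(seed, expr)

#' Derive per-item seeds from a master seed
#'
#' Deterministic, collision-resistant within a run, and kept below 2^31.
#' @noRd
derive_seeds <- function(master_seed, n) {
  with_seed(as.integer(master_seed) %% .Machine$integer.max,
            sample.int(.Machine$integer.max - 1L, n))
}

assert_rgb_image <- function(image, arg = "image") {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop(sprintf("`%s` must be an H x W x 3 array", arg), call. = FALSE)
  if (dim(image)[1] < 1L || dim(image)[2] < 1L)
    stop(sprintf("`%s` has empty spatial dimensions", arg), call. = FALSE)
  rng <- range(image)
  if (rng[1] < 0 || rng[2] > 255)
    stop(sprintf("`%s` values must lie in [0, 255]", arg), call. = FALSE)
  invisible(TRUE)
}

disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

dilate_mask <- function(mask, size = 3L) {
  storage.mode(mask) <- "double"
  EBImage::dilate(mask, EBImage::makeBrush(as.integer(size), "disc")) > 0.5
}

erode_mask <- function(mask, radius = 1L) {
  if (radius <= 0L) return(mask > 0.5)
  storage.mode(mask) <- "double"
  EBImage::erode(mask, disc_brush(radius)) > 0.5
}

#' Boundary pixels of a binary mask (pixels with a 4-neighbour outside)
#' @noRd
mask_boundary <- function(mask) {
  m <- mask > 0.5
  h <- nrow(m); w <- ncol(m)
  inner <- m
  inner[] <- FALSE
  if (h > 2 && w > 2) {
    core <- m[2:(h - 1), 2:(w - 1)] &
      m[1:(h - 2), 2:(w - 1)] & m[3:h, 2:(w - 1)] &
      m[2:(h - 1), 1:(w - 2)] & m[2:(h - 1), 3:w]
    inner[2:(h - 1), 2:(w - 1)] <- core
  }
  m & !inner
}

#' Polygonal perimeter of a binary mask via its oriented contour
#'
#' Sums unit/diagonal steps along the traced outer contour; for digital
#' disks this estimate keeps the isoperimetric compactness 4*pi*A/P^2
#' slightly below 1, as expected for a rasterised circle.
#' @noRd
mask_perimeter <- function(mask) {
  m <- mask > 0.5
  a <- sum(m)
  if (a == 0) return(0)
  if (a <= 2) return(4)  # degenerate speck
  oc <- tryCatch(EBImage::ocontour(EBImage::bwlabel(m * 1)), error = function(e) NULL)
  if (is.null(oc) || length(oc) == 0) return(4 * sqrt(a))
  per <- sum(vapply(oc, function(pts) {
    if (nrow(pts) < 3) return(4)
    nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
    sum(sqrt(rowSums((pts - nxt)^2)))
  }, numeric(1)))
  max(per, 4)
}

#' Compactness 4*pi*area/perimeter^2, capped at 1
#' @noRd
mask_compactness <- function(mask) {
  a <- sum(mask > 0.5)
  if (a == 0) return(0)
  p <- mask_perimeter(mask)
  min(4 * pi * a / p^2, 1)
}

#' Centroid of a binary mask
#' @param mask logical/0-1 matrix.
#' @return named vector `c(x = column, y = row)` of the mean pixel position.
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask > 0.5, arr.ind = TRUE)
  c(x = mean(idx[, 2]), y = mean(idx[, 1]))
}

#' z-score columns, dropping constant ones
#' @noRd
zscore_drop_constant <- function(X) {
  X <- as.matrix(X)
  sds <- apply(X, 2, sd)
  keep <- which(is.finite(sds) & sds > 0)
  if (length(keep) == 0) return(NULL)
  scale(X[, keep, drop = FALSE])
}

#' Mean silhouette width for a 2-cluster partition (Euclidean)
#'
#' Singleton clusters contribute width 1 (maximally separated point),
#' matching the use of the silhouette as a split-vs-homogeneous guard.
#' @noRd
silhouette2 <- function(X, cl) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- as.matrix(dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i]); own <- setdiff(own, i)
    oth <- which(cl != cl[i])
    if (length(own) == 0) { s[i] <- 1; next }
    a <- mean(D[i, own]); b <- mean(D[i, oth])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Ward 2-cut on z-scored features
#'
#' @return integer vector of cluster ids (1/2), or error when the cohort is
#'   indiscriminable (all feature rows identical).
#' @noRd
hclust_cut2 <- function(X) {
  Xs <- zscore_drop_constant(X)
  if (is.null(Xs))
    stop("indiscriminable cohort: all object features are identical", call. = FALSE)
  hc <- hclust(dist(Xs), method = "ward.D2")
  cutree(hc, k = 2)
}

#' Cheap stable hash of an R object (config caching / schema stamps)
#' @noRd
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  # polynomial rolling hash over the serialised bytes, 2 x 31-bit words
  v <- as.integer(raw)
  h1 <- 17; h2 <- 1234567
  m <- 2147483647
  for (chunk in split(v, ceiling(seq_along(v) / 4096))) {
    h1 <- (h1 * 31 + sum(chunk * seq_along(chunk))) %% m
    h2 <- (h2 * 131 + sum(chunk * chunk)) %% m
  }
  sprintf("%08x%08x", h1, h2)
}
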