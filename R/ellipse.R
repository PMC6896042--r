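# Candidate glandular components as fitted ellipses.
#
# Component coordinates: x = column, y = row (y grows downward); orientation
# is the angle of the major axis from the +x axis, normalised to (-pi/2, pi/2].

new_ellipse_object <- function(center, semi_major, semi_minor, orientation,
                               pixels, dim, component_class) {
  structure(list(center = center,
                 semi_major = semi_major,
                 semi_minor = semi_minor,
                 orientation = orientation,
                 pixels = as.integer(pixels),
                 dim = as.integer(dim),
                 area = length(pixels),
                 component_class = component_class,
                 is_true = NA),
            class = "ellipse_object")
}

#' Binary mask of an ellipse object
#' @param obj an `ellipse_object`.
#' @return logical matrix of the object's source image size.
#' @export
object_mask <- function(obj) {
  m <- matrix(FALSE, obj$dim[1], obj$dim[2])
  m[obj$pixels] <- TRUE
  m
}

object_centers <- function(objects) {
  t(vapply(objects, function(o) o$center, numeric(2)))
}

#' Fit ellipses to the connected components of a binary mask
#'
#' Each connected component with at least `min_area` pixels becomes a
#' candidate object; its ellipse parameters come from the component's image
#' moments (centroid plus second central moments, with the 1/12 unit-pixel
#' correction), the closed-form deterministic fit. A numeric mask is treated
#' as a graded (e.g. area-coverage) raster and its values weight the
#' moments, which preserves subpixel boundary information; for a rasterised
#' solid ellipse the fit recovers the semi-axes to a fraction of a pixel and
#' the orientation to a fraction of a degree.
#'
#' @param component_mask logical/0-1 matrix (typically an eroded cluster
#'   mask), or a numeric matrix of pixel coverage fractions in `[0, 1]`.
#' @param component_class `"PURPLE_CANDIDATE"` or `"WHITE_CANDIDATE"`.
#' @param min_area minimum component area in pixels (default 15, removing
#'   rasterisation specks at the reference scale).
#' @return list of `ellipse_object` (empty list for an empty mask).
#' @export
fit_ellipses <- function(component_mask,
                         component_class = c("PURPLE_CANDIDATE", "WHITE_CANDIDATE"),
                         min_area = 15L) {
  component_class <- match.arg(component_class)
  m <- component_mask > 0
  if (!any(m)) return(list())
  w_all <- component_mask * 1
  lab <- EBImage::bwlabel(m * 1)
  ids <- seq_len(max(lab))
  out <- list()
  for (id in ids) {
    pix <- which(lab == id)
    if (sum(w_all[pix]) < min_area) next
    rc <- arrayInd(pix, dim(m))
    fit <- moment_ellipse(x = rc[, 2], y = rc[, 1], w = w_all[pix])
    out[[length(out) + 1L]] <-
      new_ellipse_object(center = fit$center,
                         semi_major = fit$a, semi_minor = fit$b,
                         orientation = fit$theta,
                         pixels = pix, dim = dim(m),
                         component_class = component_class)
  }
  out
}

#' Moment-based ellipse parameters of a (weighted) pixel set
#' @noRd
moment_ellipse <- function(x, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  sw <- sum(w)
  mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  # 1/12 = variance of a unit pixel, so a one-pixel object has finite axes
  mu20 <- sum(w * (x - mx)^2) / sw + 1 / 12
  mu02 <- sum(w * (y - my)^2) / sw + 1 / 12
  mu11 <- sum(w * (x - mx) * (y - my)) / sw
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  if (theta <= -pi / 2) theta <- theta + pi
  if (theta > pi / 2) theta <- theta - pi
  list(center = c(x = mx, y = my),
       a = 2 * sqrt(max(l1, 1e-12)), b = 2 * sqrt(max(l2, 0)),
       theta = theta)
}

#' Rasterise an ellipse as a logical mask
#'
#' @param dim image dimensions (H, W).
#' @param center (x, y) in pixels.
#' @param a,b semi-major/semi-minor axes in pixels.
#' @param theta orientation in radians (major axis from +x).
#' @param supersample subpixel sampling factor; 1 tests pixel centres, larger
#'   values include a pixel when at least half of its `supersample^2`
#'   subsamples fall inside the ellipse (an area-coverage rasterisation).
#' @param coverage return the per-pixel coverage fractions (numeric matrix)
#'   instead of thresholding them at one half.
#' @return logical matrix (or a numeric coverage matrix).
#' @export
ellipse_mask <- function(dim, center, a, b, theta = 0, supersample = 1L,
                         coverage = FALSE) {
  H <- dim[1]; W <- dim[2]
  off <- (seq_len(supersample) - 0.5) / supersample - 0.5
  acc <- matrix(0, H, W)
  for (oy in off) for (ox in off) {
    cx <- matrix(rep(seq_len(W) + ox, each = H), H, W) - center[1]
    cy <- matrix(rep(seq_len(H) + oy, W), H, W) - center[2]
    u <- cx * cos(theta) + cy * sin(theta)
    v <- -cx * sin(theta) + cy * cos(theta)
    acc <- acc + ((u / a)^2 + (v / b)^2 <= 1)
  }
  frac <- acc / length(off)^2
  if (coverage) frac else frac >= 0.5
}

#' Overlay co-centric scaled ellipses on a detected object
#'
#' Produces `n` concentric ellipse masks centred on the object, scaled copies
#' of its fitted ellipse. With the default common orientation the masks are
#' nested (`mask_i` a subset of `mask_{i+1}`), which the annulus-based local
#' area-ratio features rely on; per-ellipse rotation offsets are available
#' but break the nesting guarantee for eccentric objects, and results are
#' then flagged. Ellipses extending beyond the image are clipped and flagged.
#'
#' @param obj an `ellipse_object`.
#' @param n number of ellipses (>= 1; default 4).
#' @param scales scale factors applied to the fitted axes (length `n`).
#' @param rotations per-ellipse orientation offsets in radians (length `n`).
#' @return list with `masks` (list of `n` logical matrices), `clipped`
#'   (logical), `nested` (logical).
#' @export
overlay_cocentric_ellipses <- function(obj, n = 4L,
                                       scales = seq(1, by = 0.5, length.out = n),
                                       rotations = rep(0, n)) {
  stopifnot(inherits(obj, "ellipse_object"))
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  stopifnot(length(scales) == n, length(rotations) == n,
            !is.unsorted(scales))
  H <- obj$dim[1]; W <- obj$dim[2]
  clipped <- FALSE
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    a <- obj$semi_major * scales[i]
    b <- obj$semi_minor * scales[i]
    th <- obj$orientation + rotations[i]
    if (obj$center[1] - a < 1 || obj$center[1] + a > W ||
        obj$center[2] - a < 1 || obj$center[2] + a > H) clipped <- TRUE
    masks[[i]] <- ellipse_mask(c(H, W), obj$center, a, b, th)
  }
  list(masks = masks, clipped = clipped, nested = all(rotations == rotations[1]))
}
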