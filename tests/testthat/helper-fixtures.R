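# Shared fixtures, built once per test session and memoised: phantom
# cohorts and their feature bundles are expensive, and several test files
# exercise different properties of the same study conditions.

.fixture_env <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# a single clean phantom + its segmentation, reused across files
fixture_phantom <- function() {
  get_fixture("phantom_clean", function() {
    s <- generate_phantom(phantom_config(seed = 42L))
    seg <- segment_image(s$image, segmentation_params(seed = 4242L))
    list(sample = s, seg = seg)
  })
}

# binary normal-vs-poor cohort bundles (the detection study conditions):
# n = 60, 30 per class, strong deformation gap
fixture_detection_bundles <- function(tag = "A", master_seed = 20260101L) {
  get_fixture(paste0("bundles_", tag), function() {
    cohort <- generate_cohort(
      list(normal = grade_config("normal"), poor = grade_config("poor")),
      n_per_class = 30L, seed = master_seed)
    seeds <- seq_along(cohort) + master_seed %% 10000L
    lapply(seq_along(cohort), function(i)
      extract_bundle(cohort[[i]]$image, label = cohort[[i]]$class_label,
                     seed = seeds[i]))
  })
}

# small raster with a rasterised solid ellipse (x = col, y = row)
raster_ellipse <- function(dim, cx, cy, a, b, theta = 0) {
  ellipse_mask(dim, c(cx, cy), a, b, theta)
}

# independent brute-force Haralick oracle, coded directly from the textbook
# double sums over the co-occurrence matrix; deliberately naive
oracle_haralick <- function(p) {
  G <- nrow(p)
  ent <- function(v) { v <- v[v > 0]; -sum(v * log(v)) }
  entropy <- 0; energy <- 0; idm <- 0; inertia <- 0; cross <- 0
  for (i in 0:(G - 1)) for (j in 0:(G - 1)) {
    pij <- p[i + 1, j + 1]
    if (pij > 0) entropy <- entropy - pij * log(pij)
    energy <- energy + pij^2
    idm <- idm + pij / (1 + (i - j)^2)
    inertia <- inertia + (i - j)^2 * pij
    cross <- cross + i * j * pij
  }
  px <- rowSums(p); py <- colSums(p)
  mux <- sum((0:(G - 1)) * px); muy <- sum((0:(G - 1)) * py)
  sx <- sqrt(sum((0:(G - 1))^2 * px) - mux^2)
  sy <- sqrt(sum((0:(G - 1))^2 * py) - muy^2)
  corr <- if (sx * sy > 1e-12) (cross - mux * muy) / (sx * sy) else 0
  psum <- numeric(2 * G - 1)   # index k+1 for k = 0..2G-2
  pdif <- numeric(G)           # index k+1 for k = 0..G-1
  for (i in 0:(G - 1)) for (j in 0:(G - 1)) {
    psum[i + j + 1] <- psum[i + j + 1] + p[i + 1, j + 1]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p[i + 1, j + 1]
  }
  ks <- 0:(2 * G - 2); kd <- 0:(G - 1)
  sum_avg <- sum(ks * psum); dif_avg <- sum(kd * pdif)
  c(entropy = entropy, energy = energy, correlation = corr,
    inverse_difference_moment = idm, inertia = inertia,
    sum_average = sum_avg, sum_entropy = ent(psum),
    sum_variance = sum((ks - sum_avg)^2 * psum),
    difference_variance = sum((kd - dif_avg)^2 * pdif),
    difference_average = dif_avg, difference_entropy = ent(pdif))
}

# exhaustive minimum total within-cluster variance 2-partition (n <= 15)
oracle_best_2partition <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  wss <- function(M) if (nrow(M) <= 1) 0 else sum(scale(M, scale = FALSE)^2)
  best <- NULL; best_val <- Inf
  for (code in 1:(2^(n - 1) - 1)) {    # fix point 1 in cluster 1
    grp <- c(1L, as.integer(intToBits(code))[1:(n - 1)] + 1L)
    val <- wss(X[grp == 1, , drop = FALSE]) + wss(X[grp == 2, , drop = FALSE])
    if (val < best_val) { best_val <- val; best <- grp }
  }
  list(partition = best, value = best_val)
}

partition_agreement <- function(a, b) {
  max(mean(a == b), mean(a == (3L - b)))
}
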