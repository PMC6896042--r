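# Pipeline orchestration and file formats: phantom dataset writer, manifest
# handling, cached end-to-end runs.

.label_vocab <- c("normal", "well", "moderate", "poor")

#' Read an RGB image file into a 0-255 array
#'
#' @param path PNG or TIFF file.
#' @return H x W x 3 array, values 0-255.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(raw)) == 2) raw <- array(rep(raw, 3), dim = c(dim(raw), 3))
  if (dim(raw)[3] > 3) raw <- raw[, , 1:3]
  round(raw * 255)
}

#' Write an RGB 0-255 array as PNG
#' @param image H x W x 3 array, values 0-255.
#' @param path output file.
#' @export
write_image <- function(image, path) {
  assert_rgb_image(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Read / write 16-bit integer label masks (TIFF)
#'
#' @param mask integer matrix (0 = background).
#' @param path file path.
#' @return `read_label_mask` returns an integer matrix.
#' @export
write_label_mask <- function(mask, path) {
  storage.mode(mask) <- "double"
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  mi <- round(m * 65535)
  storage.mode(mi) <- "integer"
  mi
}

#' Read and validate a dataset manifest
#'
#' A manifest is a CSV with columns `path`, optional `mask_path`, optional
#' `label` (from the closed vocabulary normal/well/moderate/poor), optional
#' `group`. Paths are resolved relative to the manifest location and must
#' exist.
#'
#' @param path manifest CSV.
#' @return data.frame of class `dataset_manifest`.
#' @export
read_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"path" %in% names(df))
    stop("manifest must have a 'path' column", call. = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  df$path <- resolve(df$path)
  missing <- !file.exists(df$path)
  if (any(missing))
    stop("manifest image(s) not found: ",
         paste(head(df$path[missing], 3), collapse = ", "), call. = FALSE)
  if ("mask_path" %in% names(df)) {
    has <- !is.na(df$mask_path) & nzchar(df$mask_path)
    df$mask_path[has] <- resolve(df$mask_path[has])
  }
  if ("label" %in% names(df)) {
    bad <- !is.na(df$label) & !(df$label %in% .label_vocab)
    if (any(bad))
      stop("manifest labels outside the vocabulary {",
           paste(.label_vocab, collapse = ", "), "}", call. = FALSE)
  }
  class(df) <- c("dataset_manifest", class(df))
  df
}

#' Write a phantom cohort to disk as a pipeline-ready dataset
#'
#' Writes, per sample, the PNG image, a 16-bit TIFF gland label mask and a
#' JSON sidecar (config and label), plus a manifest CSV tying them together.
#'
#' @param config_by_class named list of `phantom_config` per class label.
#' @param n_per_class samples per class.
#' @param out_dir writable output directory (created if needed).
#' @param seed master cohort seed.
#' @return path to the manifest CSV (invisibly, with the manifest attached
#'   as attribute `"manifest"`).
#' @export
make_phantom_dataset <- function(config_by_class, n_per_class, out_dir,
                                 seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create out_dir", call. = FALSE)
  samples <- generate_cohort(config_by_class, n_per_class, seed)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    stub <- sprintf("sample_%03d_%s", i, s$class_label)
    img_path <- file.path(out_dir, paste0(stub, ".png"))
    mask_path <- file.path(out_dir, paste0(stub, "_mask.tiff"))
    json_path <- file.path(out_dir, paste0(stub, ".json"))
    write_image(s$image, img_path)
    write_label_mask(s$gland_label_mask, mask_path)
    jsonlite::write_json(list(label = s$class_label,
                              config = unclass(s$config)),
                         json_path, auto_unbox = TRUE, digits = NA)
    data.frame(path = img_path, mask_path = mask_path,
               label = s$class_label, group = stub,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(out_dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(structure(mpath, manifest = manifest))
}

#' Pipeline configuration
#'
#' Centralises every stage's parameters; the configuration hash keys the
#' stage cache.
#'
#' @param bundle a [bundle_config()].
#' @param scheme a [cv_scheme()].
#' @param grid an [svm_grid()].
#' @param seed master seed for per-image feature extraction.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(bundle = bundle_config(), scheme = cv_scheme(),
                            grid = svm_grid(), seed = 1L) {
  cfg <- list(bundle = bundle, scheme = scheme, grid = grid,
              seed = as.integer(seed))
  cfg$hash <- config_hash(rapply(cfg, unclass, how = "replace"))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the end-to-end pipeline on a manifest
#'
#' Stages: per-image segmentation + feature bundling (quarantining per-image
#' failures), optional segmentation scoring against manifest masks,
#' cross-validated two-level classification, and report/feature-table
#' output. Stage outputs are cached under `out_dir` keyed by the
#' configuration hash: re-running with unchanged inputs and config is a
#' no-op (logged as cache hits).
#'
#' @param manifest a `dataset_manifest` or path to a manifest CSV.
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return list with `features` (data.frame), `report`
#'   (classification report or NULL when unlabelled), `segmentation_scores`,
#'   `quarantine` (failed image paths + reasons), `log` (stage status
#'   data.frame).
#' @export
run_pipeline <- function(manifest, config = pipeline_config(), out_dir) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  note <- function(stage, status, secs)
    log[[length(log) + 1L]] <<- data.frame(stage = stage, status = status,
                                           seconds = round(secs, 2))
  stamp_path <- file.path(out_dir, "cache_stamp.json")
  bundle_cache <- file.path(out_dir, "bundles.rds")
  input_key <- config_hash(list(manifest$path, manifest$label, config$hash))
  cache_ok <- file.exists(stamp_path) && file.exists(bundle_cache) &&
    identical(jsonlite::read_json(stamp_path)$key, input_key)

  quarantine <- data.frame(path = character(0), reason = character(0))
  cv_cached <- NULL
  if (cache_ok) {
    t0 <- proc.time()[3]
    st <- readRDS(bundle_cache)
    bundles <- st$bundles; seg_scores <- st$seg_scores
    quarantine <- st$quarantine
    cv_cached <- st$cv
    note("features", "cache hit", proc.time()[3] - t0)
  } else {
    t0 <- proc.time()[3]
    bundles <- list(); seg_scores <- list()
    seeds <- derive_seeds(config$seed, nrow(manifest))
    for (i in seq_len(nrow(manifest))) {
      res <- tryCatch({
        img <- read_image(manifest$path[i])
        par <- config$bundle$segmentation
        par$seed <- seeds[i]
        seg <- segment_image(img, par)
        if ("mask_path" %in% names(manifest) &&
            !is.na(manifest$mask_path[i]) && nzchar(manifest$mask_path[i])) {
          truth <- read_label_mask(manifest$mask_path[i])
          seg_scores[[manifest$path[i]]] <- gland_overlap_scores(seg, truth)
        }
        lab <- if ("label" %in% names(manifest)) manifest$label[i] else NA
        extract_bundle(img, label = lab, segmentation = seg,
                       config = config$bundle, seed = seeds[i])
      }, error = function(e) e)
      if (inherits(res, "error")) {
        quarantine <- rbind(quarantine,
                            data.frame(path = manifest$path[i],
                                       reason = conditionMessage(res)))
      } else bundles[[length(bundles) + 1L]] <- res
    }
    saveRDS(list(bundles = bundles, seg_scores = seg_scores,
                 quarantine = quarantine), bundle_cache)
    jsonlite::write_json(list(key = input_key), stamp_path, auto_unbox = TRUE)
    note("features", "computed", proc.time()[3] - t0)
  }

  feat_df <- do.call(rbind, lapply(bundles, function(b)
    data.frame(label = b$label,
               t(c(b$image_features,
                   b$gland_features,
                   setNames(as.vector(t(b$patch_features)),
                            paste0("patch", rep(seq_len(nrow(b$patch_features)),
                                                each = ncol(b$patch_features)),
                                   "_", colnames(b$patch_features))))),
               check.names = FALSE)))
  write.csv(feat_df, file.path(out_dir, "features.csv"), row.names = FALSE)

  report <- NULL
  labels <- vapply(bundles, function(b) as.character(b$label), "")
  if (length(bundles) >= 4 && !anyNA(labels) &&
      length(unique(labels)) >= 2 && min(table(labels)) >= 2) {
    t0 <- proc.time()[3]
    if (!is.null(cv_cached)) {
      cv <- cv_cached
    } else {
      cv <- cross_validate(bundles, config$scheme, config$grid)
      saveRDS(list(bundles = bundles, seg_scores = seg_scores,
                   quarantine = quarantine, cv = cv), bundle_cache)
    }
    report <- cv$report
    write.csv(cv$predictions, file.path(out_dir, "predictions.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(accuracy = report$accuracy, sensitivity = report$sensitivity,
           specificity = report$specificity, mcc = report$mcc,
           auc = as.list(report$auc),
           per_kernel_accuracy = as.list(cv$per_kernel_accuracy)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    note("crossval", if (!is.null(cv_cached)) "cache hit" else "computed",
         proc.time()[3] - t0)
  }
  if (nrow(quarantine) > 0)
    write.csv(quarantine, file.path(out_dir, "quarantine.csv"),
              row.names = FALSE)
  list(features = feat_df, report = report,
       segmentation_scores = seg_scores, quarantine = quarantine,
       log = do.call(rbind, log))
}
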