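#' Full pipeline configuration
#'
#' Bundles the per-stage parameters of the recognition chain: HU window,
#' ROI geometry, MIP slab depth, boundary sampling, MCA/watershed settings,
#' and classifier options.
#'
#' @param window a [window_config()].
#' @param slice_size optional `(H, W)` axial resampling before analysis
#'   (`NULL` keeps the native grid, so voxel coordinates stay valid).
#' @param radius_estimate rough nodule radius in voxels; sets the default
#'   MIP slab half-depth ("local" 3D context covering the nodule).
#' @param roi_half_extent `(rz, ry, rx)` ROI half sizes; default
#'   `radius_estimate + 10` to leave room for spicules.
#' @param slab_half_depth MIP slab half-depth; default `radius_estimate`.
#' @param n_samples angular samples for [unfold_boundary()].
#' @param min_prominence minimal protuberance prominence in pixels.
#' @param feature_len length of the resampled classifier feature vector.
#' @param mca an [mca_config()]. @param markers a [markers_config()].
#' @param knn_k neighbour count for [dtw_classify()].
#' @return An object of class `spic_config`.
#' @export
spic_config <- function(window = window_config(), slice_size = NULL,
                        radius_estimate = 10L, roi_half_extent = NULL,
                        slab_half_depth = NULL,
                        n_samples = 360L, min_prominence = 2,
                        feature_len = 64L,
                        mca = mca_config(), markers = markers_config(),
                        knn_k = 3L) {
  if (is.null(roi_half_extent))
    roi_half_extent <- rep(as.integer(radius_estimate) + 10L, 3L)
  if (is.null(slab_half_depth)) slab_half_depth <- as.integer(radius_estimate)
  structure(list(window = window, slice_size = slice_size,
                 radius_estimate = as.integer(radius_estimate),
                 roi_half_extent = as.integer(roi_half_extent),
                 slab_half_depth = as.integer(slab_half_depth),
                 n_samples = as.integer(n_samples),
                 min_prominence = min_prominence,
                 feature_len = as.integer(feature_len),
                 mca = mca, markers = markers, knn_k = as.integer(knn_k)),
            class = "spic_config")
}

#' Extract spiculation features around a nodule centre
#'
#' The feature chain shared by training and inference: crop the ROI, build
#' the tri-planar MIP, segment each view by [segment_nodule()], unfold each
#' mask with [unfold_boundary()], extract protuberances, and concatenate
#' the per-view protuberance series in fixed order (axial, coronal,
#' sagittal). Views whose segmentation fails contribute nothing.
#'
#' @param nvol a `normalized_volume`.
#' @param center nodule centre `(z, y, x)` in `nvol` coordinates.
#' @param config a [spic_config()].
#' @return List: `mip` (the `mip_triplet`), `views` (per-view segmentation,
#'   polar series, protuberances), `values` (concatenated protuberance
#'   series), `feature` (fixed-length resampled vector), `n_detected`.
#' @export
pipeline_features <- function(nvol, center, config = spic_config()) {
  stopifnot(inherits(nvol, "normalized_volume"))
  roi <- extract_roi(nvol, center, config$roi_half_extent)
  local_center <- as.integer(center) - roi$offset + nvol$offset
  mip <- triplanar_mip(roi, local_center, config$slab_half_depth)
  views <- list()
  values <- numeric(0)
  n_detected <- 0L
  for (view in c("axial", "coronal", "sagittal")) {
    img <- mip[[view]]
    seg <- segment_nodule(img, config$mca, config$markers)
    entry <- list(segmentation = seg, series = NULL, protuberances = NULL)
    if (seg$detected) {
      ok <- tryCatch({
        series <- unfold_boundary(largest_component(seg$mask),
                                  config$n_samples)
        prot <- extract_protuberances(series, config$min_prominence)
        entry$series <- series; entry$protuberances <- prot
        TRUE
      }, error = function(e) FALSE)
      if (ok) {
        n_detected <- n_detected + 1L
        values <- c(values, entry$protuberances$values)
      }
    }
    views[[view]] <- entry
  }
  list(mip = mip, views = views, values = values,
       feature = resample_series(values, config$feature_len),
       n_detected = n_detected)
}

# keep only the largest connected component of a binary mask
largest_component <- function(mask) {
  lab <- label_components((mask > 0) + 0)
  if (max(lab) <= 1L) return((mask > 0) + 0)
  counts <- tabulate(lab[lab > 0])
  (lab == which.max(counts)) + 0
}

#' Run the full spiculation-recognition pipeline on one nodule
#'
#' Normalizes the volume (if raw HU), extracts features via
#' [pipeline_features()], then classifies: by the trained adversarial
#' classifier when `model` is given, by DTW nearest neighbours when only a
#' reference `db` is given (the adversarial classifier wins when both are
#' available). All-view segmentation failure yields a report with
#' `failed = TRUE` and no label. Intermediate artifacts are written when
#' `out_dir` is given (masks and MIPs as PNG, series as CSV, the report as
#' JSON); the report itself contains no timestamps, so identical inputs
#' give identical reports.
#'
#' @param vol a [ct_volume()] (raw HU) or `normalized_volume`.
#' @param center nodule centre `(z, y, x)`, 1-based.
#' @param config a [spic_config()].
#' @param model optional `train_state` from [train_ssgan()].
#' @param db optional [reference_db()].
#' @param out_dir optional output directory for artifacts.
#' @return A `pipeline_report`.
#' @export
run_pipeline <- function(vol, center, config = spic_config(),
                         model = NULL, db = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "spic_config"))
  nvol <- if (inherits(vol, "ct_volume"))
    window_normalize(vol, config$window, config$slice_size)
  else vol
  d <- dim(nvol$voxels)
  center <- as.integer(center)
  if (any(center < 1L) || any(center > d))
    stop("nodule center lies outside the volume")

  feats <- pipeline_features(nvol, center, config)
  failed <- feats$n_detected == 0L
  dtw_res <- NULL; gan_res <- NULL; label <- NA_character_
  if (!failed) {
    if (!is.null(db)) {
      dtw_res <- dtw_classify(feats$values, db, config$knn_k)
      label <- dtw_res$label
    }
    if (!is.null(model)) {
      pr <- predict_spiculation(model, matrix(feats$feature, nrow = 1L))
      spic_col <- match("spiculated", model$classes)
      gan_res <- list(label = pr$labels[1L],
                      probability = unname(pr$probabilities[1L, spic_col]))
      label <- gan_res$label            # adversarial classifier wins
    }
  }
  report <- structure(list(
    center = center, label = label, failed = failed,
    n_views_detected = feats$n_detected,
    dtw = dtw_res[c("label", "score")],
    gan = gan_res,
    values = feats$values, feature = feats$feature,
    views = lapply(feats$views, function(v)
      list(detected = v$segmentation$detected,
           mask_area = sum(v$segmentation$mask))),
    config = config), class = "pipeline_report")
  if (!is.null(out_dir)) persist_report(report, feats, out_dir)
  report
}

persist_report <- function(report, feats, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (view in names(feats$views)) {
    seg <- feats$views[[view]]$segmentation
    png::writePNG(seg$mask * 1.0,
                  file.path(out_dir, paste0("mask_", view, ".png")))
    m <- feats$mip[[view]]
    png::writePNG(pmin(pmax(m, 0), 1),
                  file.path(out_dir, paste0("mip_", view, ".png")))
  }
  if (length(feats$values))
    utils::write.csv(data.frame(index = seq_along(feats$values),
                                value = feats$values),
                     file.path(out_dir, "series.csv"), row.names = FALSE)
  json <- list(center = report$center, label = report$label,
               failed = report$failed,
               n_views_detected = report$n_views_detected,
               dtw = report$dtw, gan = report$gan,
               views = report$views)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Build a DTW reference database from phantom samples
#'
#' Runs the feature chain on each sample and stores the concatenated
#' protuberance series with the ground-truth label.
#'
#' @param samples list of `phantom_sample`s.
#' @param config a [spic_config()].
#' @return A [reference_db()].
#' @export
build_reference_db <- function(samples, config = spic_config()) {
  series <- vector("list", length(samples))
  labels <- character(length(samples))
  for (i in seq_along(samples)) {
    f <- pipeline_features(samples[[i]]$volume,
                           round(samples[[i]]$spec$center), config)
    series[[i]] <- f$values
    labels[i] <- samples[[i]]$label
  }
  reference_db(series, labels)
}

#' Fit the adversarial classifier on phantom samples
#'
#' Extracts the fixed-length feature vector for every sample and trains
#' [train_ssgan()] with the ground-truth labels; a fraction of labels can
#' be masked to exercise the semi-supervised path.
#'
#' @param samples list of `phantom_sample`s.
#' @param config a [spic_config()].
#' @param gan a [gan_config()].
#' @param labeled_fraction fraction of samples keeping their label
#'   (masking is deterministic given `gan$seed`); stratified so each class
#'   keeps at least one label.
#' @return List `(model, features, labels)`.
#' @export
fit_pipeline_model <- function(samples, config = spic_config(),
                               gan = gan_config(), labeled_fraction = 1) {
  feats <- t(vapply(samples, function(s)
    pipeline_features(s$volume, round(s$spec$center), config)$feature,
    numeric(config$feature_len)))
  labels <- vapply(samples, `[[`, "", "label")
  y <- labels
  if (labeled_fraction < 1) {
    rng <- local_rng(gan$seed)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      keep <- max(1L, round(labeled_fraction * length(idx)))
      drop_n <- length(idx) - keep
      if (drop_n > 0) {
        u <- rng$runif(length(idx), 0, 1)
        y[idx[order(u)][seq_len(drop_n)]] <- NA
      }
    }
  }
  model <- train_ssgan(feats, y, gan)
  list(model = model, features = feats, labels = labels, masked = y)
}
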