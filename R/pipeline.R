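#' Analyse one slice image into shape-factor features
#'
#' Runs the single-image chain: sRGB -> Lab*, background thresholding,
#' optional erosion, connected components, per-slice BI/YI samples, and the
#' three-parameter Weibull fit of each sample.
#'
#' @param img Path to a PNG/TIFF image, or an H x W x 3 integer sRGB array.
#' @param thr [threshold_ranges()] for the background.
#' @param white Reference white for the Lab* conversion.
#' @param erode_radius Foreground erosion radius in pixels (edge-shading
#'   removal); 0 disables.
#' @param min_component Minimum component area in pixels.
#' @param min_n Minimum index-sample size for the Weibull fit.
#' @return data.frame with one row per detected component: component index,
#'   area, defined-pixel counts, and the fitted (alpha, beta, gamma,
#'   loglik, ks_stat, ks_p) for BI and YI.
#' @export
analyze_slice_image <- function(img, thr = threshold_ranges(),
                                white = white_point(), erode_radius = 2L,
                                min_component = 50L, min_n = 30L) {
  if (is.character(img)) img <- read_rgb_image(img)
  lab <- srgb_to_lab(img, white = white)
  mask <- segment_foreground(lab, thr)
  mask <- erode_mask(mask, erode_radius)
  comps <- extract_slices(mask, min_size = min_component)
  if (length(comps) == 0L)
    return(data.frame(component = integer(0)))
  rows <- lapply(comps, function(comp) {
    maps <- index_maps_for_slice(lab, comp)
    fit_bi <- fit_weibull3(maps$bi, min_n = min_n)
    fit_yi <- fit_weibull3(maps$yi, min_n = min_n)
    data.frame(
      component = comp$id, area = comp$n_pixels,
      n_degenerate = maps$n_degenerate,
      beta_bi = fit_bi$beta, alpha_bi = fit_bi$alpha, gamma_bi = fit_bi$gamma,
      ks_stat_bi = fit_bi$ks_stat, ks_p_bi = fit_bi$ks_p,
      beta_yi = fit_yi$beta, alpha_yi = fit_yi$alpha, gamma_yi = fit_yi$gamma,
      ks_stat_yi = fit_yi$ks_stat, ks_p_yi = fit_yi$ks_p
    )
  })
  do.call(rbind, rows)
}

#' Run the full browning-analysis pipeline over an image set
#'
#' Stages, in order: segmentation + index computation + Weibull fitting per
#' image (producing the slice-record table), jackknife classification on
#' the BI, YI and combined feature sets, and the common-slope trend fit
#' with residual diagnostics for each feature. Every intermediate table is
#' written under `out_dir`, and a manifest records the seedless input
#' hashes, configuration hash and per-stage record counts. A stage failure
#' aborts with the stage name and the offending slice id.
#'
#' @param images_dir Directory containing the images referenced by
#'   `metadata`.
#' @param metadata data.frame (or CSV path) with columns `slice_id`,
#'   `group`, `time_min`, `image` (file name relative to `images_dir`) and
#'   optionally `component` (1-based index of the slice's component within
#'   its image, default 1).
#' @param out_dir Output directory for tables and the manifest.
#' @inheritParams analyze_slice_image
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`); the slice records are in `slice_records.csv`, the
#'   classification rates in `classification.json`, the trend fits in
#'   `trend_<feature>.json`.
#' @export
run_pipeline <- function(images_dir, metadata, out_dir,
                         thr = threshold_ranges(), white = white_point(),
                         erode_radius = 2L, min_component = 50L,
                         min_n = 30L) {
  if (is.character(metadata)) metadata <- utils::read.csv(metadata)
  need <- c("slice_id", "group", "time_min", "image")
  if (!all(need %in% names(metadata)))
    stop("metadata must have columns ", paste(need, collapse = ", "))
  if (is.null(metadata$component))
    metadata$component <- rep(1L, nrow(metadata))
  imgs <- unique(metadata$image)
  if (length(imgs) == 0L || !dir.exists(images_dir))
    stop("no input images: '", images_dir, "' is empty or missing")
  missing <- imgs[!file.exists(file.path(images_dir, imgs))]
  if (length(missing) > 0L)
    stop("missing image file(s): ", paste(utils::head(missing, 3),
                                          collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  per_image <- lapply(imgs, function(f) {
    res <- tryCatch(
      analyze_slice_image(file.path(images_dir, f), thr = thr, white = white,
                          erode_radius = erode_radius,
                          min_component = min_component, min_n = min_n),
      error = function(e) stop("stage segment/index/weibull failed on image '",
                               f, "': ", conditionMessage(e), call. = FALSE))
    if (nrow(res) == 0L) return(NULL)
    res$image <- f
    res
  })
  fits <- do.call(rbind, per_image)
  if (is.null(fits) || nrow(fits) == 0L)
    stop("stage segment failed: no components found in any input image")
  records <- merge(metadata, fits, by = c("image", "component"))
  if (nrow(records) < nrow(metadata)) {
    lost <- setdiff(metadata$slice_id, records$slice_id)
    stop("stage segment failed: no component found for slice id(s) ",
         paste(utils::head(lost, 3), collapse = ", "))
  }
  records <- records[order(records$slice_id), ]
  first <- c("slice_id", "group", "time_min", "beta_bi", "beta_yi")
  records <- records[, c(first, setdiff(names(records), first))]
  utils::write.csv(records, file.path(out_dir, "slice_records.csv"),
                   row.names = FALSE)

  cls_res <- tryCatch(list(
    bi = jackknife_rate(records, "beta_bi"),
    yi = jackknife_rate(records, "beta_yi"),
    both = jackknife_rate(records, c("beta_bi", "beta_yi"))
  ), error = function(e) stop("stage classify failed: ",
                              conditionMessage(e), call. = FALSE))
  cls_json <- lapply(cls_res, function(r)
    list(per_class = as.list(r$per_class), overall = r$overall,
         sigma = r$sigma))
  jsonlite::write_json(cls_json, file.path(out_dir, "classification.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  trend_counts <- list()
  for (feature in c("beta_yi", "beta_bi")) {
    tm <- tryCatch(fit_group_lines(records, feature),
                   error = function(e) stop("stage trend failed on ", feature,
                                            ": ", conditionMessage(e),
                                            call. = FALSE))
    diag <- residual_diagnostics(tm)
    jsonlite::write_json(
      c(trend_model_json(tm),
        list(residual_mean = diag$residual_mean, bp_p = diag$bp_p,
             shapiro_p = diag$shapiro_p, ppcc = diag$ppcc,
             acf_limit = diag$acf_limit)),
      file.path(out_dir, paste0("trend_", feature, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(diag$acf,
                     file.path(out_dir, paste0("acf_", feature, ".csv")),
                     row.names = FALSE)
    utils::write.csv(diag$fitted_vs_residual,
                     file.path(out_dir, paste0("residuals_", feature, ".csv")),
                     row.names = FALSE)
    trend_counts[[feature]] <- stats::nobs(tm$parallel)
  }

  input_hashes <- tools::md5sum(file.path(images_dir, imgs))
  names(input_hashes) <- imgs
  manifest <- list(
    config = list(thresholds = unclass(thr), white = as.list(white),
                  erode_radius = erode_radius, min_component = min_component,
                  min_n = min_n),
    config_hash = hash_object(list(unclass(thr), as.numeric(white),
                                   erode_radius, min_component, min_n)),
    input_hashes = as.list(input_hashes),
    counts = list(images = length(imgs), slice_records = nrow(records),
                  bi_fits = sum(is.finite(records$beta_bi)),
                  yi_fits = sum(is.finite(records$beta_yi)),
                  trend_n = trend_counts)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# plain-list view of a trend model for JSON export
trend_model_json <- function(tm) {
  list(feature = tm$feature,
       intercepts = as.list(tm$intercepts),
       intercept_se = as.list(tm$intercept_se),
       slope = tm$slope, slope_se = tm$slope_se,
       slope_equality_p = tm$slope_equality_p,
       intercept_diff_p = tm$intercept_diff_p,
       r2_adj_pct = tm$r2_adj_pct, see = tm$see)
}

#' Per-class metric table from confusion-matrix counts
#'
#' Formats the evaluation of a binary classifier the way such results are
#' conventionally tabulated: one row per class (each class in turn taken as
#' positive), precision and recall as percentages to 2 decimals, F-measure
#' to 3 decimals, plus the overall accuracy.
#'
#' @param cm A [confusion_matrix()] for the first class taken as positive.
#' @param labels Length-2 character vector naming the positive and negative
#'   class of `cm`.
#' @return List with `table` (data.frame of formatted per-class metrics),
#'   `accuracy_pct` (numeric) and `total`.
#' @examples
#' report_metrics(confusion_matrix(2080, 0, 137, 1863), c("brown", "good"))
#' @export
report_metrics <- function(cm, labels = c("positive", "negative")) {
  m1 <- confusion_metrics(cm)
  m2 <- confusion_metrics(swap_classes(cm))
  fmt <- function(m) data.frame(
    precision_pct = round(100 * m$precision, 2),
    recall_pct = round(100 * m$recall, 2),
    f1 = round(m$f1, 3))
  tab <- cbind(class = labels, rbind(fmt(m1), fmt(m2)))
  list(table = tab, accuracy_pct = 100 * m1$accuracy, total = m1$total)
}

#' Read / write slice-record tables
#'
#' The slice-record CSV (columns `slice_id`, `group`, `time_min`,
#' `beta_bi`, `beta_yi`, ...) is the interchange format between the
#' feature-extraction stage and the statistics stages.
#'
#' @param path CSV path.
#' @param records data.frame of slice records.
#' @return `read_slice_records` the data.frame; `write_slice_records` the
#'   path, invisibly.
#' @export
read_slice_records <- function(path) {
  rec <- utils::read.csv(path)
  need <- c("slice_id", "group", "time_min")
  if (!all(need %in% names(rec)))
    stop("slice records must have columns ", paste(need, collapse = ", "))
  rec
}

#' @rdname read_slice_records
#' @export
write_slice_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
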