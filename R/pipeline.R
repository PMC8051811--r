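#' Default annotation pipeline configuration
#'
#' Namespaced settings for every stage, overridable per call:
#' `pre.*` (depth conversion), `binarize.*` (Otsu histogram), `segment.*`
#' (marker distance; the canonical choice is about 0.7 times the expected
#' nucleus radius), `filter.*` (median-area band), `noise.*` (background
#' noise of the composed training image).
#'
#' @param ... Named overrides, e.g. `segment.min_peak_distance = 10`.
#' @return Nested configuration list of class `annotate_config`.
#' @export
annotate_config <- function(...) {
  cfg <- list(
    pre = list(target_bit_depth = 8L, normalize = "percentile", p_lo = 1, p_hi = 99),
    binarize = list(n_bins = 256L),
    segment = list(min_peak_distance = 7, connectivity = 8L),
    filter = list(fraction = 0.5),
    noise = list(distribution = "gaussian", sd = 3, scope = "background_only",
                 seed = 1L))
  dots <- list(...)
  for (key in names(dots)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L || is.null(cfg[[parts[1]]]))
      abort(sprintf("unknown config key '%s'", key))
    cfg[[parts[1]]][[parts[2]]] <- dots[[key]]
  }
  structure(cfg, class = "annotate_config")
}

normalize_inputs <- function(images, ids) {
  if (is.character(images)) {
    paths <- images
    if (is.null(ids)) ids <- tools::file_path_sans_ext(basename(paths))
    loaded <- list(); ok_ids <- character(0)
    for (i in seq_along(paths)) {
      img <- tryCatch(read_image(paths[i]), error = function(e) {
        warn(sprintf("skipping unreadable image %s: %s", paths[i],
                     conditionMessage(e)))
        NULL
      })
      if (!is.null(img)) {
        loaded[[length(loaded) + 1L]] <- img
        ok_ids <- c(ok_ids, ids[i])
      }
    }
    if (length(loaded) == 0L) abort("no readable input images")
    list(images = loaded, ids = ok_ids)
  } else {
    if (is.matrix(images)) images <- list(images)
    if (is.null(ids)) ids <- sprintf("image_%03d", seq_along(images))
    list(images = images, ids = ids)
  }
}

#' Run the full automatic annotation pipeline
#'
#' Turns raw nuclei images into training-ready (image, instance-mask)
#' pairs, fully automatically: per image, depth conversion/normalization,
#' Otsu thresholding, marker-based watershed labelling; then the
#' median-area filter with the median pooled across the whole run; finally
#' composition of the training image (kept-object pixels only) with
#' background noise (per-image seeds `noise.seed + image index - 1`).
#'
#' @param images List of [intensity_image()] matrices, or a character
#'   vector of image paths (unreadable files are skipped with a warning).
#' @param output_dir If non-NULL, the dataset and reports are written here
#'   (image and label TIFFs, object CSVs, filter and run report).
#' @param config An [annotate_config()].
#' @param reference_count Optional externally known nucleus count (e.g.
#'   from manual annotation) used to report the captured fraction.
#' @param ids Optional image identifiers.
#' @return Object of class `annotation_run`: list with
#'   `pairs` (per image: `image`, `mask`, plus the pre-noise composed
#'   image), `objects` (pooled object table with `kept` flags and image
#'   ids), `filter` (the [area_filter()] result), and `report` (per-image
#'   tibble, totals, config snapshot, version).
#' @export
annotate_dataset <- function(images, output_dir = NULL,
                             config = annotate_config(),
                             reference_count = NULL, ids = NULL) {
  inp <- normalize_inputs(images, ids)
  images <- inp$images; ids <- inp$ids
  n <- length(images)
  t_run <- Sys.time()

  pre_list <- vector("list", n)
  lab_list <- vector("list", n)
  obj_list <- vector("list", n)
  per_image <- vector("list", n)
  for (i in seq_len(n)) {
    t0 <- Sys.time()
    img <- images[[i]]
    pre <- convert_depth(img, config$pre$target_bit_depth, config$pre$normalize,
                         config$pre$p_lo, config$pre$p_hi)
    ot <- otsu_threshold(pre, config$binarize$n_bins)
    mask <- apply_threshold(pre, ot$threshold)
    lab <- if (any(mask)) {
      mk <- make_markers(mask, config$segment$min_peak_distance)
      relabel_sequential(watershed_label(mask, mk))
    } else matrix(0L, nrow(pre), ncol(pre))
    obj <- object_areas(lab)
    if (nrow(obj)) obj$image <- ids[i]
    pre_list[[i]] <- pre; lab_list[[i]] <- lab; obj_list[[i]] <- obj
    per_image[[i]] <- tibble::tibble(
      image = ids[i], n_objects = nrow(obj), n_kept = NA_integer_,
      otsu_threshold = ot$threshold,
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }

  pooled <- dplyr::bind_rows(obj_list)
  if (nrow(pooled) == 0L)
    abort("no objects detected in the whole dataset; cannot annotate")
  flt <- area_filter(pooled, config$filter$fraction)

  pairs <- vector("list", n)
  per_image <- dplyr::bind_rows(per_image)
  for (i in seq_len(n)) {
    kept_ids <- flt$objects |>
      dplyr::filter(.data$image == ids[i], .data$kept) |>
      dplyr::pull("id")
    filtered <- apply_keep(lab_list[[i]], kept_ids)
    composed <- compose_training_image(pre_list[[i]], filtered)
    noisy <- add_background_noise(
      composed, filtered, config$noise$distribution, config$noise$sd,
      scope = config$noise$scope, seed = config$noise$seed + i - 1L)
    pairs[[i]] <- list(id = ids[i], image = noisy, mask = filtered,
                       composed = composed)
    per_image$n_kept[i] <- length(kept_ids)
  }

  totals <- list(
    n_total_detected = sum(per_image$n_objects),
    n_total_kept = sum(per_image$n_kept),
    captured_fraction = if (!is.null(reference_count))
      sum(per_image$n_kept) / reference_count else NA_real_,
    total_seconds = as.numeric(difftime(Sys.time(), t_run, units = "secs")),
    seconds_per_kept_object =
      as.numeric(difftime(Sys.time(), t_run, units = "secs")) /
        max(1L, sum(per_image$n_kept)))

  run <- structure(list(
    pairs = pairs, objects = flt$objects, filter = flt,
    report = list(per_image = per_image, totals = totals,
                  config = unclass(config),
                  version = as.character(packageVersion("nucann")))),
    class = "annotation_run")
  if (!is.null(output_dir)) write_annotation_run(run, output_dir)
  run
}

write_annotation_run <- function(run, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (p in run$pairs) {
    ipath <- sprintf("%s.tif", p$id); lpath <- sprintf("%s_labels.tif", p$id)
    write_image(p$image, file.path(output_dir, ipath))
    write_labelmap(p$mask, file.path(output_dir, lpath))
    entries[[length(entries) + 1L]] <-
      tibble::tibble(image = ipath, labels = lpath, split = "train")
  }
  write_object_table(run$objects, file.path(output_dir, "objects.csv"))
  write.csv(run$filter$report, file.path(output_dir, "filter_report.csv"),
            row.names = FALSE)
  jsonlite::write_json(run$report, file.path(output_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(dplyr::bind_rows(entries), output_dir,
                 file.path(output_dir, "manifest.json"))
  invisible(output_dir)
}

#' @export
print.annotation_run <- function(x, ...) {
  t <- x$report$totals
  cat(sprintf(
    "Automatic annotation run: %d image(s)\n%d objects detected, %d kept by the area filter\nmedian area %.1f px, band [%.1f, %.1f]\n",
    nrow(x$report$per_image), t$n_total_detected, t$n_total_kept,
    x$filter$report$median_area, x$filter$report$lower, x$filter$report$upper))
  if (!is.na(t$captured_fraction))
    cat(sprintf("captured fraction vs reference: %.1f%%\n",
                100 * t$captured_fraction))
  invisible(x)
}

#' Evaluate predicted label maps against ground truth
#'
#' Pools object-level confusion counts over image pairs and reports
#' precision, recall and F1 per IoU threshold (summing TP/FP/FN across
#' images before applying the formulas), plus both mean-IoU conventions.
#'
#' @param gt_maps,pred_maps Lists of label maps (or single maps), paired by
#'   position; or character vectors of label TIFF paths.
#' @param thresholds IoU thresholds, default `{0.5 ... 0.95}`.
#' @param output_dir If non-NULL, writes `metrics.csv` and `metrics.json`.
#' @return Tibble of class `f1_curve`: one row per threshold.
#' @export
evaluate_dataset <- function(gt_maps, pred_maps,
                             thresholds = c(0.50, 0.60, 0.70, 0.80, 0.90, 0.95),
                             output_dir = NULL) {
  as_maps <- function(x) {
    if (is.character(x)) lapply(x, read_labelmap)
    else if (is.matrix(x)) list(x) else x
  }
  gt_maps <- as_maps(gt_maps); pred_maps <- as_maps(pred_maps)
  if (length(gt_maps) != length(pred_maps))
    abort(sprintf("unpaired inputs: %d ground-truth vs %d predicted maps",
                  length(gt_maps), length(pred_maps)))
  mats <- purrr::map2(gt_maps, pred_maps, iou_matrix)
  out <- purrr::map_dfr(thresholds, function(t) {
    cc <- purrr::map(mats, match_at_threshold, t = t)
    tp <- sum(purrr::map_int(cc, "tp"))
    fp <- sum(purrr::map_int(cc, "fp"))
    fn <- sum(purrr::map_int(cc, "fn"))
    ious <- unlist(purrr::map(cc, ~ .x$matches$iou))
    n_gt <- sum(purrr::map_int(cc, "n_gt"))
    safe <- function(num, den) if (den > 0) num / den else 0
    tibble::tibble(t = t, tp = tp, fp = fp, fn = fn,
                   precision = safe(tp, tp + fp), recall = safe(tp, tp + fn),
                   f1 = safe(tp, tp + 0.5 * (fp + fn)),
                   mean_iou_matched = if (tp > 0) mean(ious) else 0,
                   mean_iou_all = if (n_gt > 0) sum(ious) / n_gt else 0)
  })
  class(out) <- c("f1_curve", class(out))
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out, file.path(output_dir, "metrics.csv"), row.names = FALSE)
    jsonlite::write_json(out, file.path(output_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Derived annotation-accounting ratios
#'
#' Computes the comparative ratios used to report an automatic annotation
#' run against a manual reference: the captured fraction of nuclei, the
#' per-nucleus annotation times, the total-time fraction, and the relative
#' gains in mean IoU and F1 obtained by evaluating only the automatically
#' annotated (filtered) nuclei rather than all reference nuclei.
#'
#' @param n_auto,n_reference Nuclei annotated automatically / in the
#'   reference.
#' @param auto_seconds,reference_seconds Total annotation wall-clock times.
#' @param mean_iou_restricted,mean_iou_all Mean IoU over the annotated
#'   subset vs over all reference nuclei (optional).
#' @param f1_restricted,f1_all F1 in the same two conventions (optional).
#' @return One-row tibble: `captured_fraction_pct`,
#'   `auto_seconds_per_nucleus`, `reference_seconds_per_nucleus`,
#'   `time_fraction_pct`, and (when the inputs are given)
#'   `mean_iou_gain_pct`, `f1_gain_pct`.
#' @export
annotation_summary <- function(n_auto, n_reference, auto_seconds,
                               reference_seconds,
                               mean_iou_restricted = NULL, mean_iou_all = NULL,
                               f1_restricted = NULL, f1_all = NULL) {
  if (n_auto <= 0 || n_reference <= 0) abort("nucleus counts must be positive")
  out <- tibble::tibble(
    captured_fraction_pct = 100 * n_auto / n_reference,
    auto_seconds_per_nucleus = auto_seconds / n_auto,
    reference_seconds_per_nucleus = reference_seconds / n_reference,
    time_fraction_pct = 100 * auto_seconds / reference_seconds)
  if (!is.null(mean_iou_restricted) && !is.null(mean_iou_all))
    out$mean_iou_gain_pct <-
      100 * (mean_iou_restricted - mean_iou_all) / mean_iou_all
  if (!is.null(f1_restricted) && !is.null(f1_all))
    out$f1_gain_pct <- 100 * (f1_restricted - f1_all) / f1_all
  out
}
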