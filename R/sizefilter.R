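#' Per-instance geometry table
#'
#' Measures every instance of a label map: exact pixel area, 0-based
#' half-open bounding box `[r0, r1) x [c0, c1)`, and centroid (mean of
#' 0-based pixel coordinates).
#'
#' @param labelmap Integer label map.
#' @return Tibble with columns `id`, `area_px`, `bbox_r0`, `bbox_c0`,
#'   `bbox_r1`, `bbox_c1`, `centroid_r`, `centroid_c`, `kept` (NA until a
#'   filter runs), `class` (NA unless supplied by a generator).
#' @export
object_areas <- function(labelmap) {
  labelmap <- label_map(labelmap)
  idx <- which(labelmap > 0L)
  empty <- tibble::tibble(
    id = integer(0), area_px = integer(0),
    bbox_r0 = integer(0), bbox_c0 = integer(0),
    bbox_r1 = integer(0), bbox_c1 = integer(0),
    centroid_r = numeric(0), centroid_c = numeric(0),
    kept = logical(0), class = character(0))
  if (length(idx) == 0L) return(empty)
  lab <- labelmap[idx]
  r <- (idx - 1L) %% nrow(labelmap)     # 0-based row
  c <- (idx - 1L) %/% nrow(labelmap)    # 0-based col
  tibble::tibble(id = lab, r = r, c = c) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      area_px = dplyr::n(),
      bbox_r0 = min(.data$r), bbox_c0 = min(.data$c),
      bbox_r1 = max(.data$r) + 1L, bbox_c1 = max(.data$c) + 1L,
      centroid_r = mean(.data$r), centroid_c = mean(.data$c),
      .groups = "drop") |>
    dplyr::arrange(.data$id) |>
    dplyr::mutate(kept = NA, class = NA_character_)
}

#' Median-area filter isolating the dominant single-nucleus class
#'
#' The dominant object class in a nuclei field (single nuclei) is
#' identified by the median pixel area `m` of all detected objects, pooled
#' across the whole dataset (not per image). An object is kept iff its area
#' lies inside the inclusive band
#' `[(1 - fraction) * m, (1 + fraction) * m]`; objects deviating by more
#' than `fraction * m` — merged clusters above, debris and artefacts below —
#' are excluded. The median is computed once on the unfiltered pooled
#' distribution (single pass, no iteration); for an even number of objects
#' it is the mean of the two central areas.
#'
#' @param objects An [object_areas()] tibble, or several row-bound together
#'   (add an image identifier column to keep images apart).
#' @param fraction Band half-width as a fraction of the median (default
#'   0.5), in `(0, 1)`.
#' @return List of class `filter_result`:
#'   \describe{
#'     \item{objects}{Input tibble with the `kept` flag filled in.}
#'     \item{report}{One-row tibble: `median_area`, `lower`, `upper`,
#'       `n_total`, `n_kept`, `n_excluded_small`, `n_excluded_large`.}
#'   }
#' @export
area_filter <- function(objects, fraction = 0.5) {
  if (!is.data.frame(objects)) objects <- dplyr::bind_rows(objects)
  if (nrow(objects) == 0L) abort("no objects in the dataset; nothing to filter")
  if (!(fraction > 0 && fraction < 1)) abort("`fraction` must lie in (0, 1).")
  areas <- objects$area_px
  if (any(areas <= 0)) abort("object areas must be positive")
  m <- median(areas)
  lower <- (1 - fraction) * m
  upper <- (1 + fraction) * m
  kept <- areas >= lower & areas <= upper
  objects$kept <- kept
  report <- tibble::tibble(
    median_area = m, lower = lower, upper = upper,
    n_total = length(areas), n_kept = sum(kept),
    n_excluded_small = sum(areas < lower),
    n_excluded_large = sum(areas > upper))
  structure(list(objects = objects, report = report), class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "Median-area filter: m = %.1f px, band [%.1f, %.1f]\n%d objects: %d kept, %d small excluded, %d large excluded\n",
    r$median_area, r$lower, r$upper, r$n_total, r$n_kept,
    r$n_excluded_small, r$n_excluded_large))
  invisible(x)
}

#' Keep a subset of instances in a label map
#'
#' Zeroes the pixels of all labels not in `kept_ids` and renumbers the
#' survivors sequentially.
#'
#' @param labelmap Integer label map.
#' @param kept_ids Integer vector of labels to keep (subset of the labels
#'   present).
#' @return Filtered, sequentially relabelled label map.
#' @export
apply_keep <- function(labelmap, kept_ids) {
  labelmap <- label_map(labelmap)
  extra <- setdiff(kept_ids, label_ids(labelmap))
  if (length(extra))
    abort(sprintf("kept ids not present in the label map: %s",
                  paste(head(extra, 5), collapse = ", ")))
  out <- labelmap
  out[!(out %in% as.integer(kept_ids))] <- 0L
  relabel_sequential(out)
}
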