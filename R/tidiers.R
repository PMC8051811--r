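#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname otsu_threshold
#' @param x An `otsu_result`.
#' @param ... Unused.
#' @export
tidy.otsu_result <- function(x, ...) x$scan

#' @rdname otsu_threshold
#' @export
glance.otsu_result <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, n_bins = x$n_bins,
                 n_candidates = nrow(x$scan),
                 min_sigma_w2 = min(x$scan$sigma_w2))
}

#' @rdname area_filter
#' @param x A `filter_result`.
#' @param ... Unused.
#' @export
tidy.filter_result <- function(x, ...) x$objects

#' @rdname area_filter
#' @export
glance.filter_result <- function(x, ...) x$report

#' @rdname annotate_dataset
#' @param x An `annotation_run`.
#' @param ... Unused.
#' @export
tidy.annotation_run <- function(x, ...) x$report$per_image

#' @rdname annotate_dataset
#' @export
glance.annotation_run <- function(x, ...) {
  t <- x$report$totals
  tibble::tibble(n_images = nrow(x$report$per_image),
                 n_total_detected = t$n_total_detected,
                 n_total_kept = t$n_total_kept,
                 captured_fraction = t$captured_fraction,
                 median_area = x$filter$report$median_area,
                 total_seconds = t$total_seconds)
}
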