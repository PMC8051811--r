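#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an F1-vs-IoU-threshold curve
#'
#' Line plot of the object-level F1 score across IoU thresholds, the
#' standard way to read how strictly predicted instance boundaries match
#' the ground truth: a flat curve up to high thresholds means tight
#' boundary agreement.
#'
#' @param object An `f1_curve` tibble from [f1_curve()] or
#'   [evaluate_dataset()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.f1_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$f1)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::geom_point(color = "#2166ac") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "IoU threshold", y = "F1 score",
                  title = "Object-level F1 vs IoU threshold") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.f1_curve
#' @export
plot_f1_curve <- function(object, ...) autoplot.f1_curve(object, ...)

#' Plot the object area distribution and the filter band
#'
#' Histogram of per-object pixel areas with the pooled median and the
#' inclusive keep band `[(1 - f) m, (1 + f) m]` overlaid; objects outside
#' the band (merged clusters, debris, artefacts) are the ones the filter
#' discards.
#'
#' @param object A `filter_result` from [area_filter()].
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.filter_result <- function(object, bins = 40, ...) {
  r <- object$report
  ggplot2::ggplot(object$objects, ggplot2::aes(x = .data$area_px)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", color = "grey40") +
    ggplot2::geom_vline(xintercept = r$median_area, color = "#2166ac") +
    ggplot2::geom_vline(xintercept = c(r$lower, r$upper),
                        linetype = "dashed", color = "#b2182b") +
    ggplot2::labs(x = "object area [px]", y = "count",
                  title = "Object areas and median-area filter band") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.filter_result
#' @export
plot_area_distribution <- function(object, bins = 40, ...) {
  autoplot.filter_result(object, bins = bins, ...)
}

#' Plot per-image detected vs kept object counts
#'
#' @param object An `annotation_run` from [annotate_dataset()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.annotation_run <- function(object, ...) {
  df <- object$report$per_image |>
    tidyr_pivot()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$image, y = .data$count,
                                   fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "objects",
                  title = "Detected vs kept objects per image") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

# small reshape without importing tidyr for one call
tidyr_pivot <- function(per_image) {
  dplyr::bind_rows(
    tibble::tibble(image = per_image$image, stage = "detected",
                   count = per_image$n_objects),
    tibble::tibble(image = per_image$image, stage = "kept",
                   count = per_image$n_kept))
}
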