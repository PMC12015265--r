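# ggplot2 displays for the main result types.

#' Plot bin fractions across expression percentiles
#'
#' One bar per rank-percentile bin, height the fraction of the bin's genes
#' with CVX > CVE; bars are shaded by permutation significance when the
#' permutation test has been run. A horizontal line marks 0.5 and a second
#' line the overall fraction.
#'
#' @param object A `bin_fraction_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bin_fraction_result
#' @export
autoplot.bin_fraction_result <- function(object, ...) {
  d <- object$bins
  d$significant <- if ("significant" %in% names(d)) d$significant else FALSE
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$fraction,
                                  fill = .data$significant)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = 0.5, colour = "black") +
    ggplot2::geom_hline(yintercept = object$overall_fraction, colour = "red") +
    ggplot2::scale_fill_manual(
      values = c(`FALSE` = "lightblue", `TRUE` = "darkblue"),
      name = sprintf("p < %s", format(object$alpha %||% 0.05))
    ) +
    ggplot2::labs(
      x = "gene count percentile bin",
      y = sprintf("fraction CV(%s) > CV(%s)", object$group_x, object$group_e)
    ) +
    ggplot2::theme_minimal()
}

#' Overlaid CV distributions per group
#'
#' Density-normalized histograms of the per-gene CV values of each group.
#'
#' @param cv_table A `cv_table` from [compute_cv_table()].
#' @param bins Histogram bin count.
#' @return A ggplot.
#' @export
plot_cv_histograms <- function(cv_table, bins = 60) {
  ggplot2::ggplot(
    tibble::as_tibble(cv_table),
    ggplot2::aes(x = .data$cv, fill = .data$group)
  ) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(.data$density)),
      bins = bins, alpha = 0.5, position = "identity"
    ) +
    ggplot2::labs(x = "coefficient of variation", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot a track coloured by stimulus interval
#'
#' @param object A `track_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot track_series
#' @export
autoplot.track_series <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$interval <- factor(d$interval, levels = c("before", "during", "after"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                                  colour = .data$interval)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}
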