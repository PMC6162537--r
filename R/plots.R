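#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot granulometry curves
#'
#' One cumulative structure-size curve per cell, faceted by target
#' (DNA vs DNA-free space).
#'
#' @param object a `granulometry_curve` tibble (one or many cells; bind
#'   rows to overlay populations and add a `population` column to
#'   colour by it).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot granulometry_curve
#' @export
autoplot.granulometry_curve <- function(object, ...) {
  aes <- if ("population" %in% names(object))
    ggplot2::aes(.data$radius, .data$cumulative_fraction,
                 group = .data$cell_id, colour = .data$population)
  else
    ggplot2::aes(.data$radius, .data$cumulative_fraction,
                 group = .data$cell_id)
  ggplot2::ggplot(object, aes) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$target)) +
    ggplot2::labs(x = "structure size (µm)",
                  y = "cumulative volume fraction") +
    ggplot2::theme_minimal()
}

#' Plot a pattern frequency table
#'
#' Bar chart of within-family percentages with mean +/- SD per-experiment
#' counts as labels.
#'
#' @param object a `pattern_table` from [pattern_table()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pattern_table
#' @export
autoplot.pattern_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$label, .data$percentage,
                               fill = .data$family)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f ± %.1f", .data$mean, .data$sd)),
      vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "% of cells (within family)") +
    ggplot2::theme_minimal()
}

#' Plot detected telomere spots
#'
#' Maximum-intensity-projection style scatter of spot centroids in the
#' xy plane, sized by total intensity and coloured by aggregate status.
#'
#' @param spots spot tibble from [detect_spots()] /
#'   [flag_aggregates()].
#' @return a ggplot.
#' @export
plot_spots <- function(spots) {
  aes <- if ("is_aggregate" %in% names(spots))
    ggplot2::aes(.data$x, .data$y, size = .data$total_intensity,
                 colour = .data$is_aggregate)
  else
    ggplot2::aes(.data$x, .data$y, size = .data$total_intensity)
  ggplot2::ggplot(spots, aes) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}
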