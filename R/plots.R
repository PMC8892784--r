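group_palette <- function() {
  c(C = "grey20", W = "#2c6fbb", WRF = "#c0392b")
}

#' Rose plot of rhythmic-gene phases
#'
#' Circular histogram of fitted peak phases of rhythmic genes, one
#' panel per group — the standard way to show whether rhythmic
#' expression spreads across the day or clusters at discrete times.
#'
#' @param calls A `rhythm_calls` tibble.
#' @param n_bins Number of phase bins (must divide 24 evenly).
#' @return A ggplot object.
#' @export
plot_phase_rose <- function(calls, n_bins = 24) {
  hist <- phase_histogram(calls, n_bins = n_bins)
  ggplot2::ggplot(hist, ggplot2::aes(
    x = .data$bin_start + (.data$bin_end - .data$bin_start) / 2,
    y = .data$n, fill = .data$group
  )) +
    ggplot2::geom_col(width = 24 / n_bins, colour = "white",
                      linewidth = 0.2) +
    ggplot2::coord_polar(start = 0) +
    ggplot2::scale_x_continuous(limits = c(0, 24),
                                breaks = seq(0, 18, by = 6)) +
    ggplot2::scale_fill_manual(values = group_palette(), guide = "none") +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "Peak phase (ZT, h)", y = "Rhythmic genes") +
    ggplot2::theme_minimal()
}

#' @method autoplot rhythm_calls
#' @export
autoplot.rhythm_calls <- function(object, ...) {
  plot_phase_rose(object, ...)
}

#' Bar chart of differential-expression categories
#'
#' @param screen A `de_screen` tibble.
#' @param drop_none Hide the non-significant category.
#' @return A ggplot object.
#' @export
plot_de_categories <- function(screen, drop_none = TRUE) {
  counts <- dplyr::count(screen, .data$category)
  if (drop_none) counts <- dplyr::filter(counts, .data$category != "none")
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "#c0392b") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "Genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @method autoplot de_screen
#' @export
autoplot.de_screen <- function(object, ...) {
  plot_de_categories(object, ...)
}

#' Module expression-shift overview
#'
#' Median log2 ratio with interquartile whiskers per module, against
#' the interquartile band of the null module; flagged modules are
#' highlighted.
#'
#' @param shift A [module_expression_shift()] result.
#' @return A ggplot object.
#' @export
plot_module_shift <- function(shift) {
  stopifnot(inherits(shift, "module_shift"))
  stats <- dplyr::filter(shift$stats,
                         .data$module_id != shift$null_module_id)
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$module_id,
                                      y = .data$median_log2_ratio)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = shift$m0_iqr[1], ymax = shift$m0_iqr[2],
                      alpha = 0.2, fill = "grey50") +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$iqr_low,
                                         ymax = .data$iqr_high),
                            colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$flagged), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "#c0392b")) +
    ggplot2::labs(
      x = NULL,
      y = sprintf("log2(%s / %s)", shift$group_a, shift$group_b),
      colour = "KW vs M0\np < 0.05"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @method autoplot module_shift
#' @export
autoplot.module_shift <- function(object, ...) {
  plot_module_shift(object, ...)
}

#' Cumulative distributions of normalized shift quantiles
#'
#' @param shifts A `shift_distribution` tibble (one or more rows).
#' @return A ggplot object.
#' @export
plot_shift_distribution <- function(shifts) {
  df <- tidyr::unnest(
    dplyr::select(shifts, "label", "quantiles"),
    "quantiles"
  ) |>
    group_by(.data$label) |>
    mutate(prob = (row_number() - 0.5) / n()) |>
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$quantiles, y = .data$prob,
                                   colour = .data$label)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "log2 ratio (normalized quantiles)",
                  y = "Cumulative fraction", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot shift_distribution
#' @export
autoplot.shift_distribution <- function(object, ...) {
  plot_shift_distribution(object, ...)
}
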