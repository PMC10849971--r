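# ggplot2 views of the package's result types. These are thin: each takes
# the tibble a stage returns and draws the field-standard display.

#' Plot aligned radial profiles
#'
#' One line per channel around the circularized perimeter (position 1 = the
#' alignment-channel maximum), faceted by compartment.
#'
#' @param aligned Output of [align_and_equalize()].
#' @param channels Optional subset of channels to draw.
#' @return A ggplot object.
#' @export
plot_radial_profiles <- function(aligned, channels = NULL) {
  if (!is.null(channels)) aligned <- aligned[aligned$channel %in% channels, ]
  ggplot2::ggplot(aligned, ggplot2::aes(x = .data$position, y = .data$value,
                                        colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~compartment, scales = "free_y") +
    ggplot2::labs(x = "border position (aligned)", y = "intensity (a.u.)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of axis-class proportions
#'
#' @param calls Output of [classify_polarity()].
#' @return A ggplot object.
#' @export
plot_polarity_summary <- function(calls) {
  counts <- calls %>%
    dplyr::count(.data$axis_class)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$axis_class, y = .data$n,
                                       fill = .data$axis_class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "compartments") +
    ggplot2::theme_minimal()
}

#' @describeIn z_distribution Plot a z-profile: percent-of-max per slice and
#'   channel.
#' @param object A `z_profile` tibble.
#' @param ... Unused.
#' @export
autoplot.z_profile <- function(object, ...) {
  xvar <- if ("position" %in% names(object)) "position" else "slice"
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[xvar]], y = .data$pct_of_max,
                                       colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "z-slice (1 = bottom)", y = "% of channel maximum",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn jaccard_diff_score Histogram of the empirical null with the
#'   observed delta marked.
#' @param object A `jaccard_diff` object.
#' @param ... Unused.
#' @export
autoplot.jaccard_diff <- function(object, ...) {
  df <- tibble(delta = object$null_deltas)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$delta, colour = "red") +
    ggplot2::labs(x = "null j2 - j1", y = "count",
                  subtitle = sprintf("observed delta = %.3f, empirical p = %.3g",
                                     object$delta, object$empirical_p)) +
    ggplot2::theme_minimal()
}

#' @describeIn pairwise_comparison_matrix Heatmap of `-log10(q)` for the
#'   query x reference comparison matrix.
#' @param object An `overlap_matrix` tibble.
#' @param ... Unused.
#' @export
autoplot.overlap_matrix <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$reference, y = .data$query,
                                       fill = .data$neg_log10_q)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "-log10(q)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
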