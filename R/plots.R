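#' Plot a zero-offset-correction fit
#'
#' Three stacked panels in the style TDR analysts expect: the input
#' series, the per-step filter outputs converging on the surface
#' estimate, and the corrected depth. `surface_zoom` restricts the
#' y-axis of the filter panel to the surface region so the estimate is
#' visible next to deep dives.
#'
#' @param object a `zoc_filter`.
#' @param surface_zoom optional `c(lower, upper)` metres for the filter
#'   panel's y-axis; defaults to the fit's `depth_bounds` when set.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot zoc_filter
#' @export
autoplot.zoc_filter <- function(object, surface_zoom = NULL, ...) {
  aug <- augment(object)
  step_cols <- paste0("step_", seq_along(object$k))
  long <- aug |>
    tidyr::pivot_longer(c("input", dplyr::all_of(step_cols), "corrected"),
                        names_to = "series", values_to = "depth") |>
    dplyr::mutate(panel = dplyr::case_when(
      .data$series == "input" ~ "A. input",
      .data$series == "corrected" ~ "C. corrected",
      TRUE ~ "B. filters"))
  long$panel <- factor(long$panel,
                       c("A. input", "B. filters", "C. corrected"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$index, y = .data$depth,
                                     colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.2, na.rm = TRUE) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Sample index", y = "Depth (m)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a correction evaluation
#'
#' Density of the deviations of corrected from clean depth, with the
#' reference Gaussian noise density overlaid: if the correction were
#' perfect the two curves would coincide.
#'
#' @param object a `zoc_eval`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot zoc_eval
#' @export
autoplot.zoc_eval <- function(object, ...) {
  dev <- attr(object, "deviations")
  sig <- object$sigma
  ggplot2::ggplot(tibble(deviation = dev),
                  ggplot2::aes(x = .data$deviation)) +
    ggplot2::geom_density(colour = "black") +
    ggplot2::stat_function(fun = stats::dnorm,
                           args = list(mean = 0, sd = sig),
                           colour = "red") +
    ggplot2::labs(x = "Deviation from clean depth (m)", y = "Density") +
    ggplot2::theme_minimal()
}
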