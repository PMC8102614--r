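#' Posterior densities of a fitted model
#'
#' Density of each reported parameter's posterior draws, faceted by
#' parameter, with the posterior median marked.
#'
#' @param object A `yawn_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.yawn_fit <- function(object, ...) {
  glev <- object$group_levels
  G <- if (identical(glev, "")) 1L else length(glev)
  core <- core_parameters(object$spec, G, glev)
  long <- tidyr::pivot_longer(object$draws[core], dplyr::everything(),
                              names_to = "term", values_to = "value")
  meds <- long |> group_by(.data$term) |>
    summarise(median = median(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_vline(data = meds,
                        ggplot2::aes(xintercept = .data$median),
                        linetype = 2) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "posterior draw", y = "density") +
    ggplot2::theme_minimal()
}

#' Slope summaries across measures and models
#'
#' Point-interval plot of the posterior slope (median and 90% CI) for
#' every (clade, measure, model) combination in a tidied summary table.
#'
#' @param summaries A tibble of [tidy.yawn_measure_result()] rows,
#'   optionally with a `clade` column.
#' @return A ggplot object.
#' @export
plot_effects <- function(summaries) {
  slopes <- filter(summaries, grepl("^beta_", .data$term))
  if (!"clade" %in% names(slopes)) slopes$clade <- "all"
  ggplot2::ggplot(slopes,
                  ggplot2::aes(x = .data$median, y = .data$measure,
                               color = .data$model)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_lower, xmax = .data$ci_upper),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_wrap(~clade) +
    ggplot2::labs(x = "slope per SD of predictor (log-seconds)",
                  y = NULL, color = "model") +
    ggplot2::theme_minimal()
}

#' Species yawn duration against a brain measure
#'
#' Scatter of species mean yawn duration (log scale) against a log
#' brain measure, colored by clade.
#'
#' @param data Species-level table from [aggregate_species()].
#' @param measure Brain measure name (default `"brain_mass"`).
#' @return A ggplot object.
#' @export
plot_duration_vs_brain <- function(data, measure = "brain_mass") {
  log_col <- measure_log_col(measure)
  ggplot2::ggplot(data,
                  ggplot2::aes(x = .data[[log_col]],
                               y = .data$mean_duration,
                               color = .data$clade)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = paste0(log_col, " (log g or log count)"),
                  y = "mean yawn duration (s, log scale)") +
    ggplot2::theme_minimal()
}
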