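#' Plot the step-assignment summary
#'
#' Bar chart of the share of the table resolved by each annotation step.
#'
#' @param summary Tibble from [summarize_steps()].
#' @return A ggplot object.
#' @export
plot_step_summary <- function(summary) {
  ggplot2::ggplot(summary, ggplot2::aes(x = .data$step, y = .data$pct)) +
    ggplot2::geom_col(fill = "#4477AA") +
    ggplot2::labs(x = "annotation step", y = "% of foods",
                  title = "Foods resolved per annotation step") +
    ggplot2::theme_minimal()
}

#' Plot predicted vs known free sugar
#'
#' Scatter of model predictions against known values with the identity line;
#' the panel caption carries the Pearson r and MAE of the comparison.
#'
#' @param data Tibble with prediction and truth columns.
#' @param predicted,truth Columns (tidy-select).
#' @return A ggplot object.
#' @export
plot_validation <- function(data, predicted, truth) {
  report <- evaluate_predictions(data, {{ predicted }}, {{ truth }})
  ggplot2::ggplot(data, ggplot2::aes(x = {{ truth }}, y = {{ predicted }})) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.4, colour = "#4477AA") +
    ggplot2::labs(
      x = "known free sugar (g/100 g)", y = "predicted free sugar (g/100 g)",
      caption = sprintf("n = %d, Pearson r = %.3f, MAE = %.2f g/100 g",
                        report$n, report$pearson_r, report$mae)
    ) +
    ggplot2::theme_minimal()
}

#' Plot intake by an ordinal grouping
#'
#' Weighted group means with +/- 2 SE error bars, the visual companion of
#' [weighted_trend()] for wealth-gradient tables.
#'
#' @param data Tibble with outcome, group and weight columns.
#' @param values,groups,weights Columns (tidy-select).
#' @return A ggplot object.
#' @export
plot_group_means <- function(data, values, groups, weights) {
  est <- data |>
    dplyr::filter(!is.na({{ groups }})) |>
    dplyr::group_by(group = {{ groups }}) |>
    dplyr::group_modify(~ weighted_mean_se(.x, {{ values }}, {{ weights }})) |>
    dplyr::ungroup()
  ggplot2::ggplot(est, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - 2 * .data$se,
                                          ymax = .data$mean + 2 * .data$se),
                             colour = "#4477AA") +
    ggplot2::labs(x = NULL, y = "weighted mean (+/- 2 SE)") +
    ggplot2::theme_minimal()
}
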