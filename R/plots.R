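#' Plot the per-patient cost distribution
#'
#' Histogram of six-month per-patient total (or healthcare) costs — the
#' figure that makes the cost skew visible: most patients cluster near
#' zero while a small sick-leave-driven tail carries most of the cohort
#' cost.
#'
#' @param summaries Patient cost summaries from [cost_patients()].
#' @param component Column to plot, default `"total"`.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_cost_distribution <- function(summaries, component = "total",
                                   bins = 40) {
  stopifnot(component %in% names(summaries))
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data[[component]])) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = paste0("six-month ", component, " cost (EUR)"),
                  y = "patients",
                  title = "Distribution of per-patient costs") +
    ggplot2::theme_minimal()
}

#' Tornado plot of sensitivity scenarios
#'
#' Horizontal bars of the percent change in total (or healthcare) cost per
#' scenario, ordered by absolute impact — the standard display of a
#' deterministic one-way/multi-way sensitivity analysis.
#'
#' @param sens A [scenario_table()] result.
#' @param outcome `"total"` or `"healthcare"`.
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(sens, outcome = c("total", "healthcare")) {
  outcome <- match.arg(outcome)
  col <- paste0("pct_change_", outcome)
  df <- sens |>
    filter(.data$scenario != "Base case scenario") |>
    mutate(scenario = stats::reorder(.data$scenario, abs(.data[[col]])))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[col]], y = .data$scenario)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = paste0("% change in ", outcome, " cost"), y = NULL,
                  title = "Deterministic sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' Plot episode duration bands
#'
#' Bar chart of treatment-episode duration categories (0-6 weeks, 7-12
#' weeks, 12-26 weeks, over 6 months).
#'
#' @param episode_table The `episode_table` element of a [coi_analyze()]
#'   result.
#' @return A ggplot object.
#' @export
plot_episode_durations <- function(episode_table) {
  ggplot2::ggplot(episode_table,
                  ggplot2::aes(x = .data$duration_category, y = .data$n)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::labs(x = "treatment duration", y = "patients",
                  title = "Treatment-episode durations") +
    ggplot2::theme_minimal()
}
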