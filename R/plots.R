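#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a staircase track
#'
#' Presented level against trial number, with correct/incorrect responses
#' marked and the phase switch indicated.
#'
#' @param object a `task_result` from [run_task()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.task_result <- function(object, ...) {
  trials <- object$trials
  if (all(is.na(trials$level))) {
    abort(sprintf("Task %s has no tracked levels to plot.", object$task_id))
  }
  ggplot2::ggplot(trials, ggplot2::aes(x = .data$trial, y = .data$level)) +
    ggplot2::geom_step(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$correct), size = 2) +
    ggplot2::geom_vline(xintercept = object$spec$switch_trial + 0.5,
                        linetype = "dashed", colour = "grey60") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2c7fb8",
                                            `FALSE` = "#d95f02"),
                                 name = "correct") +
    ggplot2::labs(
      title = sprintf("%s (%s) staircase", object$task_id, object$version),
      x = "trial",
      y = sprintf("tracked level (%s)", object$spec$tracked_quantity)
    ) +
    ggplot2::theme_minimal()
}

#' Bland-Altman agreement plot
#'
#' @param ba_data a tibble as produced in a study report's `bland_altman`
#'   element (columns `pair`, `task`, `measure`, `pair_mean`, `pct_diff`).
#' @param tasks optional subset of tasks to display.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(ba_data, tasks = NULL) {
  if (!is.null(tasks)) ba_data <- ba_data %>% filter(.data$task %in% tasks)
  ggplot2::ggplot(ba_data,
                  ggplot2::aes(x = .data$pair_mean, y = .data$pct_diff,
                               colour = .data$pair)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~ task + measure, scales = "free_x") +
    ggplot2::labs(x = "mean of pair", y = "percentage difference (%)") +
    ggplot2::theme_minimal()
}

#' Reliability overview plot
#'
#' ICC per task measure, with the conventional fair/good/excellent guides.
#'
#' @param reliability a reliability table from [reliability_table()].
#' @return A ggplot object.
#' @export
plot_reliability <- function(reliability) {
  d <- reliability %>%
    mutate(label = ifelse(.data$measure == "rt_isv",
                          paste0(.data$task, " (ISV)"), .data$task))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$label, .data$icc),
                                  y = .data$icc)) +
    ggplot2::geom_hline(yintercept = c(0.4, 0.6, 0.75),
                        linetype = "dotted", colour = "grey60") +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "ICC(A,k)") +
    ggplot2::theme_minimal()
}
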