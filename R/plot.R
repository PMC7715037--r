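#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_point
#'   geom_vline geom_col labs scale_fill_gradient theme_minimal
#'   scale_x_continuous facet_wrap
#' @importFrom rlang .data
#' @export
ggplot2::autoplot

#' Plot a confusion matrix as a heat map
#'
#' @param object An `ss_confusion`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ss_confusion <- function(object, ...) {
  df <- tidy.ss_confusion(object)
  ggplot(df, aes(x = .data$decoded, y = .data$intended,
                 fill = .data$probability)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "steelblue4", limits = c(0, 1)) +
    labs(x = "decoded target", y = "intended target",
         title = "Calibration confusion matrix") +
    theme_minimal()
}

#' Plot a trial-length plan
#'
#' Capacity and information rate against the candidate analysis window,
#' with the chosen length marked.
#'
#' @param object An `ss_trial_length_plan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ss_trial_length_plan <- function(object, ...) {
  df <- tidy.ss_trial_length_plan(object)
  long <- tidyr::pivot_longer(df, c("capacity_bits", "rate_bits_per_s"),
                              names_to = "quantity", values_to = "value")
  ggplot(long, aes(x = .data$length_s, y = .data$value)) +
    geom_line() + geom_point() +
    geom_vline(xintercept = attr(object, "chosen_length_s"),
               linetype = "dashed") +
    facet_wrap(~ .data$quantity, scales = "free_y", ncol = 1) +
    labs(x = "trial length (s)", y = NULL,
         title = "Adaptive trial-length selection") +
    theme_minimal()
}

#' Alternating-treatments accuracy plot
#'
#' Session-by-session accuracy, condition-coded, with a dashed line
#' separating the baseline phase from the comparison phase (supply
#' `baseline_sessions` to place it).
#'
#' @param object An `ss_condition_summary`.
#' @param metric Which per-session metric to plot, default
#'   `"accuracy_incl_backspace"`.
#' @param baseline_sessions Number of leading baseline sessions; the phase
#'   line is drawn after them. `NULL` (default) draws no line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ss_condition_summary <- function(object,
                                          metric = "accuracy_incl_backspace",
                                          baseline_sessions = NULL, ...) {
  sessions <- attr(object, "sessions")
  p <- ggplot(sessions, aes(x = .data$session_index, y = .data[[metric]],
                            colour = .data$condition,
                            group = .data$condition)) +
    geom_line() + geom_point(size = 2) +
    scale_x_continuous(breaks = sessions$session_index) +
    labs(x = "session", y = metric, colour = "condition",
         title = "Copy-spelling performance by session") +
    theme_minimal()
  if (!is.null(baseline_sessions)) {
    p <- p + geom_vline(xintercept = baseline_sessions + 0.5,
                        linetype = "dashed")
  }
  p
}

#' Selection-category counts per condition
#'
#' @param summary An `ss_condition_summary`.
#' @return A ggplot bar chart of correct-letter / correct-backspace /
#'   incorrect counts by condition.
#' @export
plot_selection_categories <- function(summary) {
  sessions <- attr(summary, "sessions")
  long <- sessions |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      correct_letter = sum(.data$n_correct_letters),
      correct_backspace = sum(.data$n_correct_backspaces),
      incorrect = sum(.data$n_incorrect), .groups = "drop"
    ) |>
    tidyr::pivot_longer(-"condition", names_to = "category",
                        values_to = "count")
  ggplot(long, aes(x = .data$condition, y = .data$count,
                   fill = .data$category)) +
    geom_col(position = "stack") +
    labs(x = NULL, y = "selections",
         title = "Selection categories by condition") +
    theme_minimal()
}
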