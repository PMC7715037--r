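#' Dependent-variable metrics of one copy-spelling session
#'
#' Computes the per-session dependent variables: selection counts by
#' category; accuracy including correct backspaces (the primary accuracy,
#' in percent); accuracy counting only correctly typed letters; and three
#' characters-per-minute measures over active typing time (breaks between
#' words excluded) -- total CPM (all selections), correct CPM including
#' letters and backspace, and correct CPM for letters only.
#'
#' Sessions terminated by the early-stop rule with no selections at all
#' still produce a metrics row (zero counts, 0% accuracy); a log with no
#' selections and no stop event is an error.
#'
#' @param log An `ss_session_log`.
#' @return A one-row tibble of class `ss_session_metrics` with columns
#'   `condition`, `n_correct_letters`, `n_correct_backspaces`,
#'   `n_incorrect`, `n_selections`, `accuracy_incl_backspace`,
#'   `accuracy_letters_only`, `cpm_total`, `ccpm_letters_and_backspace`,
#'   `ccpm_letters_only`, `active_typing_minutes`.
#' @export
#' @examples
#' # a hand-built log: 6 correct letters, 1 correct backspace, 2 incorrect
#' # over 10 active minutes gives accuracies 77.8% / 66.7% and
#' # CPM 0.9 / 0.7 / 0.6
compute_metrics <- function(log) {
  if (!inherits(log, "ss_session_log")) {
    abort("`log` must be an ss_session_log", class = "ss_invalid_log")
  }
  active_s <- attr(log, "active_typing_time_s")
  sel <- log[log$event == "selection", ]
  stopped <- any(log$event == "stop")
  if (nrow(sel) == 0L) {
    if (!stopped) {
      abort("empty session: no selections recorded",
            class = "ss_empty_session")
    }
    if (is.null(active_s) || active_s <= 0) {
      abort("invalid log: nonpositive active typing time",
            class = "ss_invalid_log")
    }
    counts <- c(correct_letter = 0L, correct_backspace = 0L, incorrect = 0L)
  } else {
    if (is.null(active_s) || active_s <= 0) {
      abort("invalid log: nonpositive active typing time",
            class = "ss_invalid_log")
    }
    counts <- c(
      correct_letter = sum(sel$category == "correct_letter"),
      correct_backspace = sum(sel$category == "correct_backspace"),
      incorrect = sum(sel$category == "incorrect")
    )
  }
  total <- sum(counts)
  minutes <- active_s / 60
  acc_incl <- if (total > 0) {
    100 * (counts[["correct_letter"]] + counts[["correct_backspace"]]) / total
  } else {
    0
  }
  acc_letters <- if (total > 0) 100 * counts[["correct_letter"]] / total else 0
  out <- tibble::tibble(
    condition = attr(log, "condition") %||% NA_character_,
    n_correct_letters = counts[["correct_letter"]],
    n_correct_backspaces = counts[["correct_backspace"]],
    n_incorrect = counts[["incorrect"]],
    n_selections = total,
    accuracy_incl_backspace = acc_incl,
    accuracy_letters_only = acc_letters,
    cpm_total = total / minutes,
    ccpm_letters_and_backspace =
      (counts[["correct_letter"]] + counts[["correct_backspace"]]) / minutes,
    ccpm_letters_only = counts[["correct_letter"]] / minutes,
    active_typing_minutes = minutes
  )
  structure(out, class = c("ss_session_metrics", class(out)))
}

#' Per-condition summaries of session metrics
#'
#' Mean, minimum and maximum of every metric within each condition, plus
#' the session-by-session table used for alternating-treatments plots
#' (session index vs accuracy, condition coded).
#'
#' @param logs A list of `ss_session_log` objects, or a tibble of metric
#'   rows as returned by [compute_metrics()] (stacked).
#' @return An `ss_condition_summary`: tibble with one row per condition and
#'   metric (`condition`, `metric`, `mean`, `min`, `max`, `n_sessions`),
#'   with the per-session table as attribute `sessions`.
#' @export
summarize_conditions <- function(logs) {
  sessions <- if (is.data.frame(logs)) {
    tibble::as_tibble(logs)
  } else {
    dplyr::bind_rows(lapply(logs, compute_metrics))
  }
  if (nrow(sessions) == 0L) stop_invalid("no sessions to summarise")
  sessions$session_index <- seq_len(nrow(sessions))
  metric_cols <- c("accuracy_incl_backspace", "accuracy_letters_only",
                   "cpm_total", "ccpm_letters_and_backspace",
                   "ccpm_letters_only", "n_selections")
  long <- tidyr::pivot_longer(
    sessions[, c("condition", metric_cols)],
    dplyr::all_of(metric_cols), names_to = "metric", values_to = "value"
  )
  out <- long |>
    dplyr::group_by(.data$condition, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value), min = min(.data$value),
      max = max(.data$value), n_sessions = dplyr::n(), .groups = "drop"
    )
  structure(out, class = c("ss_condition_summary", class(out)),
            sessions = sessions)
}

#' Write session metrics to CSV
#'
#' Accuracies are exported rounded to one decimal place (full precision is
#' retained in the in-memory objects).
#'
#' @param metrics A tibble of metric rows.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  out <- dplyr::mutate(
    tibble::as_tibble(metrics),
    dplyr::across(dplyr::starts_with("accuracy"), ~ round(.x, 1))
  )
  readr::write_csv(out, path)
  invisible(path)
}
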