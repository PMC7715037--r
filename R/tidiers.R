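#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a confusion matrix
#'
#' @param x An `ss_confusion`.
#' @param ... Unused.
#' @return A tibble with `intended`, `decoded`, `probability`.
#' @export
tidy.ss_confusion <- function(x, ...) {
  mat <- unclass(x)
  tibble::tibble(
    intended = rep(seq_len(nrow(mat)), times = ncol(mat)),
    decoded = rep(seq_len(ncol(mat)), each = nrow(mat)),
    probability = as.numeric(mat)
  )
}

#' @rdname tidy.ss_confusion
#' @export
glance.ss_confusion <- function(x, ...) {
  tibble::tibble(
    k = nrow(x),
    diagonal_mean = mean(diag(unclass(x))),
    n_trials = sum(attr(x, "n_trials")),
    smoothing = attr(x, "smoothing"),
    capacity_bits = nykopp_capacity(x)$capacity_bits
  )
}

#' Tidy a capacity result
#'
#' @param x An `ss_capacity`.
#' @param ... Unused.
#' @return A tibble with one row per input symbol and its optimal input
#'   probability.
#' @export
tidy.ss_capacity <- function(x, ...) {
  tibble::tibble(
    input = seq_along(x$optimal_input_distribution),
    optimal_probability = x$optimal_input_distribution
  )
}

#' @rdname tidy.ss_capacity
#' @export
glance.ss_capacity <- function(x, ...) {
  tibble::tibble(
    capacity_bits = x$capacity_bits,
    iterations = x$iterations,
    converged = x$converged
  )
}

#' Tidy a trial-length plan
#'
#' @param x An `ss_trial_length_plan`.
#' @param ... Unused.
#' @return The candidate-length table as a plain tibble.
#' @export
tidy.ss_trial_length_plan <- function(x, ...) {
  tibble::tibble(length_s = x$length_s, capacity_bits = x$capacity_bits,
                 rate_bits_per_s = x$rate_bits_per_s)
}

#' @rdname tidy.ss_trial_length_plan
#' @export
glance.ss_trial_length_plan <- function(x, ...) {
  tibble::tibble(
    chosen_length_s = attr(x, "chosen_length_s"),
    overhead_s = attr(x, "overhead_s"),
    degenerate = attr(x, "degenerate"),
    max_rate_bits_per_s = max(x$rate_bits_per_s)
  )
}

#' Tidy a fitted KDE likelihood model
#'
#' @param x An `ss_kde_model`.
#' @param ... Unused.
#' @return A tibble with one row per (target, frequency) density:
#'   `intended_target`, `frequency_index`, `bandwidth`, `n`.
#' @export
tidy.ss_kde_model <- function(x, ...) {
  rows <- purrr::imap(x$densities, function(dens_t, nm) {
    tibble::tibble(
      intended_target = as.integer(sub("target_", "", nm)),
      frequency_index = seq_along(dens_t),
      bandwidth = purrr::map_dbl(dens_t, "bandwidth"),
      n = purrr::map_int(dens_t, "n")
    )
  })
  dplyr::bind_rows(rows)
}

#' Tidy a session log
#'
#' @param x An `ss_session_log`.
#' @param ... Unused.
#' @return The event tibble with the condition attached as a column.
#' @export
tidy.ss_session_log <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$condition <- attr(x, "condition")
  out
}

#' @rdname tidy.ss_session_log
#' @export
glance.ss_session_log <- function(x, ...) {
  tibble::as_tibble(compute_metrics(x))
}
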