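#' Build the harmonic reference bank for CCA scoring
#'
#' For each stimulation frequency f the bank holds sine and cosine rows at
#' h\[&times;\]f for harmonics h = 1..n_harmonics, sampled at `rate_hz` for
#' `duration_s` seconds.  With the defaults (2 harmonics) each frequency
#' contributes four rows: sin(2&pi;ft), cos(2&pi;ft), sin(4&pi;ft),
#' cos(4&pi;ft).
#'
#' @param stimulus_set An [stimulus_set()].
#' @param duration_s Segment duration in seconds.
#' @param rate_hz Sampling rate in Hz.
#' @return An object of class `ss_reference_bank`: a list with one
#'   `2*n_harmonics x n_samples` matrix per frequency, plus `duration_s`,
#'   `rate_hz` and `frequencies_hz`.
#' @export
#' @examples
#' bank <- build_reference_bank(stimulus_set(), duration_s = 6, rate_hz = 256)
#' dim(bank$references[[1]])
build_reference_bank <- function(stimulus_set, duration_s, rate_hz = 256) {
  check_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  n <- round(duration_s * rate_hz)
  n_rows <- 2L * stimulus_set$n_harmonics
  if (n < 2L * n_rows) {
    stop_invalid("segment too short for the requested number of harmonics")
  }
  t <- (seq_len(n) - 1) / rate_hz
  refs <- lapply(stimulus_set$frequencies_hz, function(f) {
    rows <- lapply(seq_len(stimulus_set$n_harmonics), function(h) {
      rbind(sin(2 * pi * h * f * t), cos(2 * pi * h * f * t))
    })
    do.call(rbind, rows)
  })
  structure(
    list(references = refs, duration_s = duration_s, rate_hz = rate_hz,
         frequencies_hz = stimulus_set$frequencies_hz),
    class = "ss_reference_bank"
  )
}

# First canonical correlation between two variable sets, columns = variables.
# Rank-tolerant: both sets are centred and whitened through an SVD keeping
# components with singular value > rank_tol * largest, so duplicated or
# constant columns cannot destabilise the estimate.
first_canonical_correlation <- function(X, Y, rank_tol = 1e-9) {
  X <- sweep(X, 2, colMeans(X))
  Y <- sweep(Y, 2, colMeans(Y))
  sx <- svd(X)
  sy <- svd(Y)
  kx <- sum(sx$d > rank_tol * max(sx$d, 0))
  ky <- sum(sy$d > rank_tol * max(sy$d, 0))
  if (kx == 0L || ky == 0L) return(NA_real_)  # degenerate input
  M <- crossprod(sx$u[, seq_len(kx), drop = FALSE],
                 sy$u[, seq_len(ky), drop = FALSE])
  r <- svd(M, nu = 0, nv = 0)$d[1]
  min(max(r, 0), 1)
}

#' Canonical correlation scores of an EEG segment against a reference bank
#'
#' For each stimulation frequency, computes the first (largest) canonical
#' correlation between the full channel set of the segment and that
#' frequency's sin/cos harmonic references.  Scores lie in \[0, 1\], are
#' invariant to channel order and to per-channel affine rescaling, and a
#' noise-free response at frequency f scores 1 at f.  A constant
#' (rank-deficient) segment scores 0 at every frequency and carries a
#' `degenerate` flag with a warning.
#'
#' @param segment An [eeg_segment()].
#' @param bank A [build_reference_bank()] result of matching duration and
#'   rate.
#' @return An object of class `ss_cca_scores`: numeric vector of
#'   per-frequency scores with attributes `segment_duration_s` and
#'   `degenerate`.
#' @export
#' @examples
#' seg <- generate_ssvep_trial(1, 2, snr = Inf, seed = 1)
#' bank <- build_reference_bank(stimulus_set(), 2)
#' cca_scores(seg, bank)
cca_scores <- function(segment, bank) {
  n <- ncol(segment$samples)
  if (n != round(bank$duration_s * bank$rate_hz) ||
      segment$rate_hz != bank$rate_hz) {
    stop_invalid("segment duration/rate must match the reference bank")
  }
  if (nrow(segment$samples) < 1L) stop_invalid("segment must have >= 1 channel")
  X <- t(segment$samples)  # time x channels
  scores <- vapply(bank$references, function(ref) {
    first_canonical_correlation(X, t(ref))
  }, numeric(1))
  degenerate <- anyNA(scores)
  if (degenerate) {
    warn("degenerate (constant) segment; CCA scores set to 0",
         class = "ss_degenerate_input")
    scores[is.na(scores)] <- 0
  }
  structure(scores, segment_duration_s = bank$duration_s,
            degenerate = degenerate, class = "ss_cca_scores")
}

#' @export
print.ss_cca_scores <- function(x, ...) {
  cat("<ss_cca_scores>", paste(sprintf("%.4f", unclass(x)), collapse = " "),
      sprintf(" (%.3g s)\n", attr(x, "segment_duration_s")))
  invisible(x)
}

#' Score a calibration set
#'
#' Computes [cca_scores()] for every trial of a calibration tibble, at the
#' recorded duration or any truncation of it.  This single scoring path is
#' also what adaptive trial-length selection re-uses at each candidate
#' length.
#'
#' @param calibration Tibble from [generate_ssvep_calibration()] (columns
#'   `trial_id`, `intended_target`, `segment`).
#' @param stimulus_set The [stimulus_set()] used for the recordings.
#' @param duration_s Analysis window in seconds; trials are truncated to
#'   their first `duration_s` seconds. Default: full recorded duration.
#' @return A tibble with `trial_id`, `intended_target`, `duration_s`, and
#'   one `score_f<k>` column per stimulation frequency.
#' @export
#' @examples
#' calib <- generate_ssvep_calibration(n_per_target = 5, duration_s = 1,
#'                                     snr = Inf, seed = 1)
#' cca_score_table(calib, stimulus_set())
cca_score_table <- function(calibration, stimulus_set, duration_s = NULL) {
  if (nrow(calibration) == 0L) stop_invalid("empty calibration table")
  seg1 <- calibration$segment[[1]]
  full <- segment_duration(seg1)
  if (is.null(duration_s)) duration_s <- full
  if (duration_s > full + 1e-9) {
    stop_invalid("`duration_s` exceeds the recorded trial length")
  }
  bank <- build_reference_bank(stimulus_set, duration_s, seg1$rate_hz)
  scores <- purrr::map(calibration$segment, function(seg) {
    seg_t <- if (duration_s < segment_duration(seg)) {
      truncate_segment(seg, duration_s)
    } else {
      seg
    }
    as.numeric(cca_scores(seg_t, bank))
  })
  mat <- do.call(rbind, scores)
  colnames(mat) <- paste0("score_f", seq_along(stimulus_set$frequencies_hz))
  dplyr::bind_cols(
    tibble::tibble(trial_id = calibration$trial_id,
                   intended_target = calibration$intended_target,
                   duration_s = duration_s),
    tibble::as_tibble(mat)
  )
}
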