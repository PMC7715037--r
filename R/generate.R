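#' Construct an EEG segment object
#'
#' A fixed-rate multichannel block of EEG samples (microvolt scale) used for
#' calibration and query trials.
#'
#' @param samples Numeric matrix, channels x time.
#' @param rate_hz Sampling rate in Hz.
#' @param channel_labels Channel names; default occipital montage
#'   `c("O1", "Oz", "O2")` truncated/recycled to the number of rows.
#' @param quality_flags Logical per channel, `TRUE` when the channel is
#'   artifact-contaminated.
#' @return An object of class `ss_eeg_segment`.
#' @export
eeg_segment <- function(samples, rate_hz = 256,
                        channel_labels = NULL, quality_flags = NULL) {
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop_invalid("`samples` must be a numeric channels x time matrix.")
  }
  check_number(rate_hz, "rate_hz", min = 0, strict_min = TRUE)
  n_ch <- nrow(samples)
  if (is.null(channel_labels)) {
    channel_labels <- if (n_ch == 3L) c("O1", "Oz", "O2") else
      paste0("ch", seq_len(n_ch))
  }
  if (length(channel_labels) != n_ch) {
    stop_invalid("`channel_labels` must have one entry per channel.")
  }
  if (is.null(quality_flags)) quality_flags <- rep(FALSE, n_ch)
  structure(
    list(samples = samples, rate_hz = rate_hz,
         channel_labels = as.character(channel_labels),
         quality_flags = as.logical(quality_flags)),
    class = "ss_eeg_segment"
  )
}

#' @export
print.ss_eeg_segment <- function(x, ...) {
  cat(sprintf("<ss_eeg_segment> %d channel(s) x %d samples @ %g Hz (%.3g s)\n",
              nrow(x$samples), ncol(x$samples), x$rate_hz,
              ncol(x$samples) / x$rate_hz))
  if (any(x$quality_flags)) {
    cat("  flagged channels:",
        paste(x$channel_labels[x$quality_flags], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.ss_eeg_segment <- function(x, ...) {
  n <- ncol(x$samples)
  out <- tibble::tibble(time_s = (seq_len(n) - 1) / x$rate_hz)
  for (i in seq_len(nrow(x$samples))) {
    out[[x$channel_labels[i]]] <- x$samples[i, ]
  }
  out
}

# duration in seconds
segment_duration <- function(segment) ncol(segment$samples) / segment$rate_hz

# Truncate a segment to its first `duration_s` seconds
truncate_segment <- function(segment, duration_s) {
  n <- round(duration_s * segment$rate_hz)
  if (n < 1 || n > ncol(segment$samples)) {
    stop_invalid("truncation length outside the recorded segment")
  }
  eeg_segment(segment$samples[, seq_len(n), drop = FALSE], segment$rate_hz,
              segment$channel_labels, segment$quality_flags)
}

# 1/f-amplitude-shaped Gaussian noise, one channel, unit RMS
pink_noise <- function(n, rate_hz) {
  white <- rnorm(n)
  spec <- stats::fft(white)
  freq <- seq(0, n - 1) / n * rate_hz
  freq <- pmin(freq, rate_hz - freq)  # two-sided
  shape <- ifelse(freq > 0, 1 / pmax(freq, 1), 0)  # flat below 1 Hz
  shaped <- Re(stats::fft(spec * shape, inverse = TRUE)) / n
  rms <- sqrt(mean(shaped^2))
  if (rms == 0) shaped else shaped / rms
}

#' Generate a synthetic SSVEP trial
#'
#' Emulates the EEG recorded while a user attends one of the four flickering
#' targets: channel-specific sinusoids at the target's stimulation frequency
#' and its harmonics (second harmonic at half the fundamental amplitude by
#' default), superposed on 1/f-shaped broadband noise.  The signal-to-noise
#' ratio is RMS(signal)/RMS(noise) per channel; `snr = 0` yields pure noise
#' and `snr = Inf` a noise-free trial.  Output is a pure function of the
#' arguments including `seed`.
#'
#' @param intended_target Target index 1-4 (top, bottom, left, right).
#' @param duration_s Trial duration in seconds (> 0); calibration trials are
#'   recorded for 6 s.
#' @param snr Per-channel RMS signal-to-noise ratio (>= 0, may be `Inf`).
#' @param stimulus_set An [stimulus_set()] object.
#' @param rate_hz Sampling rate, default 256 Hz.
#' @param seed Integer seed; identical calls give bit-identical output.
#' @param harmonic_ratio Amplitude of harmonic h relative to the fundamental
#'   (`harmonic_ratio^(h-1)`); default 0.5.
#' @return An [eeg_segment()].
#' @export
#' @examples
#' trial <- generate_ssvep_trial(1, duration_s = 2, snr = 1, seed = 1)
#' trial
generate_ssvep_trial <- function(intended_target, duration_s, snr = 1,
                                 stimulus_set = shufflespeller::stimulus_set(),
                                 rate_hz = 256, seed,
                                 harmonic_ratio = 0.5) {
  check_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_number(snr, "snr", min = 0, allow_inf = TRUE)
  if (!is.numeric(intended_target) || length(intended_target) != 1L ||
      !(intended_target %in% 1:4)) {
    stop_invalid("`intended_target` must be one of 1, 2, 3, 4.")
  }
  if (missing(seed)) stop_invalid("`seed` is required.")
  f0 <- stimulus_set$frequencies_hz[intended_target]
  n_h <- stimulus_set$n_harmonics
  if (rate_hz <= 2 * f0 * n_h) {
    stop_invalid("`rate_hz` must exceed twice the highest harmonic frequency.")
  }
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  n_ch <- 3L

  with_seed(seed, {
    gains <- runif(n_ch, 0.8, 1.2)
    phases <- matrix(runif(n_ch * n_h, 0, 2 * pi), n_ch, n_h)
    samples <- matrix(0, n_ch, n)
    for (ch in seq_len(n_ch)) {
      sig <- rep(0, n)
      for (h in seq_len(n_h)) {
        sig <- sig + harmonic_ratio^(h - 1) *
          sin(2 * pi * h * f0 * t + phases[ch, h])
      }
      sig <- gains[ch] * sig
      noise <- pink_noise(n, rate_hz)
      sig_rms <- sqrt(mean(sig^2))
      if (is.infinite(snr)) {
        samples[ch, ] <- sig
      } else if (snr == 0) {
        samples[ch, ] <- noise
      } else {
        # scale noise so RMS(signal)/RMS(noise) = snr on this channel
        samples[ch, ] <- sig + noise * (sig_rms / snr)
      }
    }
    # nominal 10 uV scale
    eeg_segment(10 * samples, rate_hz)
  })
}

#' Generate a synthetic gaze trail
#'
#' Emulates eye-tracker output while the user fixates one of the four target
#' boxes: points scattered isotropically (bivariate normal) around the target
#' centre, with i.i.d. Bernoulli sample dropouts marked invalid.
#'
#' @param intended_target Target index 1-4.
#' @param duration_s Duration in seconds; calibration gaze trials last 3 s.
#' @param scatter_deg Isotropic standard deviation of the gaze scatter in
#'   degrees of visual angle.
#' @param dropout_rate Probability in `[0, 1)` that a sample is invalid.
#' @param layout A [screen_layout()].
#' @param rate_hz Sampling rate, default 60 Hz.
#' @param seed Integer seed.
#' @return A tibble of class `ss_gaze_trail` with columns `time_s`, `x`, `y`,
#'   `valid`, and attributes `rate_hz` and `intended_target`.
#' @export
#' @examples
#' generate_gaze_trial(1, duration_s = 1, scatter_deg = 1, seed = 1)
generate_gaze_trial <- function(intended_target, duration_s, scatter_deg = 1,
                                dropout_rate = 0,
                                layout = screen_layout(), rate_hz = 60, seed) {
  check_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_number(scatter_deg, "scatter_deg", min = 0)
  if (!is.numeric(dropout_rate) || length(dropout_rate) != 1L ||
      is.na(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1) {
    stop_invalid("`dropout_rate` must be in [0, 1).")
  }
  if (!(intended_target %in% 1:4)) {
    stop_invalid("`intended_target` must be one of 1, 2, 3, 4.")
  }
  if (missing(seed)) stop_invalid("`seed` is required.")
  n <- round(duration_s * rate_hz)
  ctr <- box_center(layout, intended_target)
  with_seed(seed, {
    out <- tibble::tibble(
      time_s = (seq_len(n) - 1) / rate_hz,
      x = ctr[1] + rnorm(n, sd = scatter_deg),
      y = ctr[2] + rnorm(n, sd = scatter_deg),
      valid = runif(n) >= dropout_rate
    )
    structure(out, class = c("ss_gaze_trail", class(out)),
              rate_hz = rate_hz, intended_target = intended_target)
  })
}

#' Inject high-amplitude artifact bursts into an EEG segment
#'
#' Reproduces the intermittent, high-amplitude non-EEG transients that can
#' contaminate occipital recordings in the field.  Burst onsets follow a
#' Poisson process at `burst_rate` events per minute; each burst hits one
#' randomly chosen channel with a short tapered transient scaled to
#' `amplitude_factor` times that channel's pre-injection peak, and sets the
#' channel's quality flag.  `burst_rate = 0` returns the input unchanged.
#'
#' @param segment An [eeg_segment()].
#' @param burst_rate Expected bursts per minute (>= 0).
#' @param amplitude_factor Peak burst amplitude relative to the channel's
#'   pre-injection peak absolute amplitude.
#' @param seed Integer seed.
#' @return An [eeg_segment()] with bursts added and `quality_flags` set on
#'   affected channels.
#' @export
inject_artifacts <- function(segment, burst_rate, amplitude_factor = 50,
                             seed) {
  check_number(burst_rate, "burst_rate", min = 0)
  check_number(amplitude_factor, "amplitude_factor", min = 0)
  if (burst_rate == 0) return(segment)
  if (missing(seed)) stop_invalid("`seed` is required.")
  n <- ncol(segment$samples)
  n_ch <- nrow(segment$samples)
  dur <- segment_duration(segment)
  with_seed(seed, {
    n_bursts <- rpois(1, burst_rate * dur / 60)
    samples <- segment$samples
    flags <- segment$quality_flags
    if (n_bursts > 0) {
      burst_len <- max(3L, round(0.1 * segment$rate_hz))  # ~100 ms
      shape <- sin(pi * seq_len(burst_len) / (burst_len + 1))  # taper
      shape <- shape / max(shape)
      for (b in seq_len(n_bursts)) {
        ch <- sample.int(n_ch, 1)
        start <- sample.int(max(1L, n - burst_len + 1L), 1)
        idx <- start:min(n, start + burst_len - 1L)
        peak <- max(abs(segment$samples[ch, ]))
        if (peak == 0) peak <- 1
        sgn <- sample(c(-1, 1), 1)
        # burst overwrites the channel (amplifier-saturation style), so the
        # flagged channel's peak is amplitude_factor x its clean peak
        samples[ch, idx] <- sgn * amplitude_factor * peak *
          shape[seq_along(idx)]
        flags[ch] <- TRUE
      }
    }
    eeg_segment(samples, segment$rate_hz, segment$channel_labels, flags)
  })
}

#' Generate a full SSVEP calibration set
#'
#' Calibration presents each of the four targets in turn; 20 trials per
#' target of 6 s each is the standard protocol.  Per-trial seeds are derived
#' deterministically from `seed`.
#'
#' @param n_per_target Trials per target, default 20.
#' @param duration_s Trial duration, default 6 s.
#' @inheritParams generate_ssvep_trial
#' @param artifact_rate Bursts per minute passed to [inject_artifacts()]
#'   (0 = clean).
#' @param amplitude_factor Artifact amplitude factor.
#' @return A tibble with columns `trial_id`, `intended_target`, `seed` and a
#'   list-column `segment` of [eeg_segment()] objects.
#' @export
#' @examples
#' calib <- generate_ssvep_calibration(n_per_target = 5, duration_s = 1,
#'                                     snr = 2, seed = 1)
#' calib
generate_ssvep_calibration <- function(n_per_target = 20, duration_s = 6,
                                       snr = 1,
                                       stimulus_set =
                                         shufflespeller::stimulus_set(),
                                       rate_hz = 256, seed,
                                       artifact_rate = 0,
                                       amplitude_factor = 50) {
  if (missing(seed)) stop_invalid("`seed` is required.")
  grid <- tidyr::expand_grid(intended_target = 1:4,
                             rep = seq_len(n_per_target))
  grid$trial_id <- seq_len(nrow(grid))
  grid$seed <- as.integer((seed * 1009L + grid$trial_id * 7919L) %% .Machine$integer.max)
  grid$segment <- purrr::map2(grid$intended_target, grid$seed, function(tg, s) {
    seg <- generate_ssvep_trial(tg, duration_s, snr, stimulus_set, rate_hz,
                                seed = s)
    if (artifact_rate > 0) {
      seg <- inject_artifacts(seg, artifact_rate, amplitude_factor,
                              seed = s + 1L)
    }
    seg
  })
  dplyr::select(grid, "trial_id", "intended_target", "seed", "segment")
}

#' Generate a gaze calibration set
#'
#' @param n_per_target Trials per target, default 20.
#' @param duration_s Gaze trial duration, default 3 s.
#' @inheritParams generate_gaze_trial
#' @return A tibble with `trial_id`, `intended_target`, `seed` and a
#'   list-column `trail`.
#' @export
generate_gaze_calibration <- function(n_per_target = 20, duration_s = 3,
                                      scatter_deg = 1, dropout_rate = 0.05,
                                      layout = screen_layout(), rate_hz = 60,
                                      seed) {
  if (missing(seed)) stop_invalid("`seed` is required.")
  grid <- tidyr::expand_grid(intended_target = 1:4,
                             rep = seq_len(n_per_target))
  grid$trial_id <- seq_len(nrow(grid))
  grid$seed <- as.integer((seed * 2003L + grid$trial_id * 6007L) %% .Machine$integer.max)
  grid$trail <- purrr::map2(grid$intended_target, grid$seed, function(tg, s) {
    generate_gaze_trial(tg, duration_s, scatter_deg, dropout_rate, layout,
                        rate_hz, seed = s)
  })
  dplyr::select(grid, "trial_id", "intended_target", "seed", "trail")
}

#' Write / read an EEG trial as CSV plus JSON sidecar
#'
#' One row per sample, one column per channel, with a `time_s` column; the
#' sidecar (same path with extension `.json`) records the sampling rate,
#' channel labels, quality flags and any supplied metadata.
#'
#' @param segment An [eeg_segment()].
#' @param path Output CSV path.
#' @param metadata Named list stored in the sidecar (e.g. target, seed, snr).
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(segment, path, metadata = list()) {
  readr::write_csv(as_tibble.ss_eeg_segment(segment), path)
  side <- c(list(rate_hz = segment$rate_hz,
                 channel_labels = segment$channel_labels,
                 quality_flags = segment$quality_flags),
            metadata)
  jsonlite::write_json(side, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trial_csv
#' @return For `read_trial_csv()`, an [eeg_segment()] with the sidecar
#'   metadata attached as attribute `metadata`.
#' @export
read_trial_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  side <- jsonlite::read_json(sub("\\.csv$", ".json", path),
                              simplifyVector = TRUE)
  labs <- side$channel_labels
  samples <- t(as.matrix(df[, labs, drop = FALSE]))
  dimnames(samples) <- NULL
  seg <- eeg_segment(samples, side$rate_hz, labs, side$quality_flags)
  extra <- side[setdiff(names(side),
                        c("rate_hz", "channel_labels", "quality_flags"))]
  attr(seg, "metadata") <- extra
  seg
}
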