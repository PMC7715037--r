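#' Full run configuration
#'
#' One object carrying every knob of the pipeline; all defaults are
#' resolvable without user input, and the resolved configuration is
#' serialised into every output directory for provenance.
#'
#' @param condition Session condition tag (`"SSBCI"` default).
#' @param seed Master seed; stage seeds are derived from it.
#' @param snr Generator signal-to-noise ratio for SSVEP trials.
#' @param scatter_deg,dropout_rate Gaze generator parameters.
#' @param artifact_rate Artifact bursts per minute in calibration trials.
#' @param n_calibration_per_target Calibration trials per target (20
#'   standard).
#' @param calibration_duration_s Recorded calibration trial length (6 s).
#' @param candidate_lengths_s Trial-length candidate grid.
#' @param overhead_s Rate-denominator overhead (2 s inter-query pause).
#' @param smoothing Confusion-matrix pseudo-count.
#' @param n_words Words per session (5).
#' @param session Extra arguments passed to [session_config()].
#' @return An `ss_run_config` list.
#' @export
run_config <- function(condition = "SSBCI", seed = 1L, snr = 1,
                       scatter_deg = 1, dropout_rate = 0.05,
                       artifact_rate = 0,
                       n_calibration_per_target = 20,
                       calibration_duration_s = 6,
                       candidate_lengths_s = seq(1, 6, by = 0.5),
                       overhead_s = 2.0, smoothing = 0.5,
                       n_words = 5, session = list()) {
  cfg <- list(condition = condition, seed = as.integer(seed), snr = snr,
              scatter_deg = scatter_deg, dropout_rate = dropout_rate,
              artifact_rate = artifact_rate,
              n_calibration_per_target = n_calibration_per_target,
              calibration_duration_s = calibration_duration_s,
              candidate_lengths_s = candidate_lengths_s,
              overhead_s = overhead_s, smoothing = smoothing,
              n_words = n_words, session = session)
  structure(cfg, class = "ss_run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror [run_config()] arguments.
#' @return An `ss_run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Calibration stage
#'
#' Generates (or accepts) a calibration set, scores it, fits the KDE model
#' and estimates the leave-one-out confusion matrix; optionally writes the
#' scores CSV, fitted-model JSON and confusion CSV into `out_dir`.
#'
#' @param config An [run_config()].
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param calibration Optional pre-generated calibration tibble.
#' @return A list: `calibration`, `scores`, `model`, `confusion`.
#' @export
calibrate <- function(config = run_config(), out_dir = NULL,
                      calibration = NULL) {
  sset <- stimulus_set()
  if (is.null(calibration)) {
    calibration <- generate_ssvep_calibration(
      n_per_target = config$n_calibration_per_target,
      duration_s = config$calibration_duration_s,
      snr = config$snr, stimulus_set = sset, seed = config$seed,
      artifact_rate = config$artifact_rate
    )
  }
  scores <- cca_score_table(calibration, sset)
  model <- fit_kde_model(scores)
  confusion <- estimate_confusion(scores, smoothing = config$smoothing)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(scores, file.path(out_dir, "calibration_scores.csv"))
    write_kde_model(model, file.path(out_dir, "kde_model.json"))
    conf_df <- as.data.frame(unclass(confusion))
    readr::write_csv(tibble::as_tibble(conf_df),
                     file.path(out_dir, "confusion.csv"))
  }
  list(calibration = calibration, scores = scores, model = model,
       confusion = confusion)
}

#' Run the full pipeline for one session
#'
#' Calibrate, choose the trial length, simulate one copy-spelling session
#' under the configured condition, and compute its metrics.  When
#' `out_dir` is given, every artifact (scores, model, confusion,
#' trial-length plan, session log, metrics, resolved config) is written
#' there along with a checksummed manifest.
#'
#' @param config An [run_config()].
#' @param out_dir Optional output directory.
#' @return A list: `calibration` (as [calibrate()]), `plan`, `log`,
#'   `metrics`, `word_list`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  condition <- config$condition
  if (!(condition %in% c("C1.2", "C2.5", "SSET", "SSBCI"))) {
    stop_invalid("invalid condition tag")
  }
  sset <- stimulus_set()
  word_list <- sample_word_lists(1, seed = config$seed)[[1]][
    seq_len(config$n_words)]
  scfg_args <- c(list(condition = condition, seed = config$seed + 17L),
                 config$session)
  scfg <- do.call(session_config, scfg_args)

  cal <- NULL
  plan <- NULL
  if (condition %in% c("SSET", "SSBCI")) {
    cal <- calibrate(config, out_dir = out_dir)
    plan <- select_trial_length(
      cal$calibration, sset,
      candidate_lengths_s = config$candidate_lengths_s,
      overhead_s = config$overhead_s, smoothing = config$smoothing
    )
    trial_len <- attr(plan, "chosen_length_s")
    user <- make_bci_user(cal$model, sset, snr = config$snr,
                          trial_length_s = trial_len,
                          seed = config$seed + 101L)
    log <- run_copy_session(scfg, user, word_list,
                            confusion = cal$confusion)
  } else {
    log <- run_copy_session(scfg, list(scatter_deg = config$scatter_deg),
                            word_list)
  }
  metrics <- compute_metrics(log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(plan)) {
      write_trial_length_plan(plan, file.path(out_dir, "trial_length_plan.json"))
    }
    write_session_log(log, file.path(out_dir, "session_log.jsonl"))
    write_metrics_csv(metrics, file.path(out_dir, "metrics.csv"))
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
    write_manifest(out_dir)
  }
  list(calibration = cal, plan = plan, log = log, metrics = metrics,
       word_list = word_list)
}

# Checksummed manifest of every artifact in a run directory
write_manifest <- function(out_dir) {
  files <- setdiff(list.files(out_dir), "manifest.csv")
  man <- tibble::tibble(
    file = files,
    md5 = as.character(tools::md5sum(file.path(out_dir, files)))
  )
  readr::write_csv(man, file.path(out_dir, "manifest.csv"))
  invisible(man)
}
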