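# Gaussian-kernel KDE with Silverman's rule, stored as points + bandwidth.
# A floor on the bandwidth keeps degenerate (zero-variance) calibration
# samples usable: the density collapses to a narrow peak instead of a delta.
kde_1d <- function(x, bandwidth = NULL, bw_floor = 0.01) {
  stopifnot(length(x) >= 1)
  if (is.null(bandwidth)) {
    # a zero-spread sample collapses to a narrow peak at the floor width
    # (bw.nrd0's own fallback would scale with the datum's magnitude)
    spread <- stats::sd(x)
    bandwidth <- if (!is.finite(spread) || spread == 0) {
      bw_floor
    } else {
      max(tryCatch(stats::bw.nrd0(x), error = function(e) 0), bw_floor)
    }
  }
  list(x = as.numeric(x), bandwidth = bandwidth, n = length(x))
}

kde_eval <- function(kde, at) {
  vapply(at, function(a) mean(dnorm(a, mean = kde$x, sd = kde$bandwidth)),
         numeric(1))
}

#' Fit per-target, per-frequency KDE likelihood models
#'
#' For each (intended target t, stimulation frequency k) pair, fits a
#' one-dimensional Gaussian-kernel density (Silverman's rule bandwidth) to
#' the CCA scores at frequency k observed when the user attends target t --
#' 16 densities for the 4-target speller.  The class-conditional likelihood
#' of a score vector s under target t is the product over frequencies of
#' density(t, k) at s\[k\] (frequencies treated as independent).
#'
#' @param calibration_scores Tibble from [cca_score_table()]: one row per
#'   trial with `intended_target` and `score_f*` columns.
#' @param bw_floor Minimum bandwidth; guards against zero-variance samples.
#' @param min_trials Minimum trials per target (default 5; leave-one-out
#'   refits relax this by one internally).
#' @return An object of class `ss_kde_model`.
#' @export
#' @examples
#' calib <- generate_ssvep_calibration(n_per_target = 5, duration_s = 1,
#'                                     snr = Inf, seed = 1)
#' model <- calib |> cca_score_table(stimulus_set()) |> fit_kde_model()
#' model
fit_kde_model <- function(calibration_scores, bw_floor = 0.01,
                          min_trials = 5L) {
  score_cols <- grep("^score_f", names(calibration_scores), value = TRUE)
  if (length(score_cols) == 0L) {
    stop_invalid("`calibration_scores` must contain score_f* columns")
  }
  targets <- sort(unique(calibration_scores$intended_target))
  counts <- table(calibration_scores$intended_target)
  too_few <- names(counts)[counts < min_trials]
  if (length(too_few) > 0) {
    abort(
      paste0("insufficient calibration: fewer than 5 trials for target(s) ",
             paste(too_few, collapse = ", ")),
      class = "ss_insufficient_calibration"
    )
  }
  densities <- lapply(targets, function(tg) {
    rows <- calibration_scores[calibration_scores$intended_target == tg, ]
    lapply(score_cols, function(col) kde_1d(rows[[col]], bw_floor = bw_floor))
  })
  names(densities) <- paste0("target_", targets)
  structure(
    list(densities = densities, targets = targets, score_cols = score_cols,
         n_per_target = as.integer(counts[as.character(targets)]),
         bw_floor = bw_floor),
    class = "ss_kde_model"
  )
}

#' @export
print.ss_kde_model <- function(x, ...) {
  cat(sprintf("<ss_kde_model> %d targets x %d frequencies (%d densities)\n",
              length(x$targets), length(x$score_cols),
              length(x$targets) * length(x$score_cols)))
  cat("  trials per target:", paste(x$n_per_target, collapse = ", "), "\n")
  invisible(x)
}

#' Class-conditional likelihoods of an observation
#'
#' Evaluates the fitted model at an observed feature vector and returns one
#' unnormalised likelihood per intended target.  For an `ss_kde_model` the
#' observation is a CCA score vector (one score per stimulation frequency);
#' for an `ss_gaze_model` it is a gaze feature (x, y).  Densities are
#' floored at 1e-12 so the returned vector is strictly positive.
#'
#' @param model A fitted `ss_kde_model` or `ss_gaze_model`.
#' @param observed Numeric feature vector matching the model's dimension.
#' @return Numeric vector of K nonnegative likelihoods (K targets).
#' @export
class_likelihoods <- function(model, observed) {
  UseMethod("class_likelihoods")
}

#' @export
class_likelihoods.ss_kde_model <- function(model, observed) {
  observed <- as.numeric(observed)
  if (length(observed) != length(model$score_cols)) {
    stop_invalid("`observed` must have one score per stimulation frequency")
  }
  vapply(model$densities, function(dens_t) {
    prod(vapply(seq_along(observed), function(k) {
      max(kde_eval(dens_t[[k]], observed[k]), 1e-12)
    }, numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
}

# ---- gaze likelihood model --------------------------------------------------

# 20%-trimmed mean gaze position over valid samples; trials with < 25% valid
# samples yield NA and are treated as unrecognized.
gaze_trial_feature <- function(trail, trim = 0.2, validity_floor = 0.25) {
  ok <- trail$valid
  if (mean(ok) < validity_floor) return(c(NA_real_, NA_real_))
  c(mean(trail$x[ok], trim = trim), mean(trail$y[ok], trim = trim))
}

#' Summarise gaze calibration trials into per-trial features
#'
#' The per-trial feature is the 20%-trimmed mean of valid gaze samples;
#' trials with fewer than 25% valid samples are flagged unrecognized
#' (`NA` feature).
#'
#' @param calibration Tibble from [generate_gaze_calibration()].
#' @return Tibble with `trial_id`, `intended_target`, `gx`, `gy`,
#'   `valid_fraction`, `recognized`.
#' @export
gaze_feature_table <- function(calibration) {
  feats <- purrr::map(calibration$trail, gaze_trial_feature)
  tibble::tibble(
    trial_id = calibration$trial_id,
    intended_target = calibration$intended_target,
    gx = purrr::map_dbl(feats, 1),
    gy = purrr::map_dbl(feats, 2),
    valid_fraction = purrr::map_dbl(calibration$trail, ~ mean(.x$valid)),
    recognized = !is.na(purrr::map_dbl(feats, 1))
  )
}

#' Fit a per-target gaze likelihood model
#'
#' A bivariate Gaussian-product-kernel density over the per-trial robust
#' mean gaze position, one density per intended target.
#'
#' @param gaze_features Tibble from [gaze_feature_table()].
#' @param bw_floor Minimum bandwidth in degrees.
#' @param min_trials Minimum recognized trials per target.
#' @return An object of class `ss_gaze_model`.
#' @export
fit_gaze_model <- function(gaze_features, bw_floor = 0.1, min_trials = 5L) {
  feats <- gaze_features[gaze_features$recognized, ]
  targets <- sort(unique(gaze_features$intended_target))
  counts <- table(feats$intended_target)
  too_few <- setdiff(as.character(targets),
                     names(counts)[counts >= min_trials])
  if (length(too_few) > 0) {
    abort(
      paste0("insufficient calibration: fewer than 5 recognized trials for ",
             "target(s) ", paste(too_few, collapse = ", ")),
      class = "ss_insufficient_calibration"
    )
  }
  densities <- lapply(targets, function(tg) {
    rows <- feats[feats$intended_target == tg, ]
    list(x = kde_1d(rows$gx, bw_floor = bw_floor),
         y = kde_1d(rows$gy, bw_floor = bw_floor))
  })
  names(densities) <- paste0("target_", targets)
  structure(list(densities = densities, targets = targets,
                 bw_floor = bw_floor),
            class = "ss_gaze_model")
}

#' @export
class_likelihoods.ss_gaze_model <- function(model, observed) {
  observed <- as.numeric(observed)
  if (length(observed) != 2L) {
    stop_invalid("`observed` must be a gaze point c(x, y)")
  }
  if (anyNA(observed)) return(rep(0, length(model$targets)))
  vapply(model$densities, function(d) {
    max(kde_eval(d$x, observed[1]), 1e-12) *
      max(kde_eval(d$y, observed[2]), 1e-12)
  }, numeric(1), USE.NAMES = FALSE)
}

# ---- confusion matrix -------------------------------------------------------

#' Estimate the intended-vs-decoded confusion matrix
#'
#' Leave-one-out estimate: each calibration trial is classified by the
#' argmax class likelihood of a model fitted without that trial; counts are
#' accumulated per (intended, decoded) pair, Laplace-smoothed by
#' `smoothing`, and rows normalised to 1.  The default pseudo-count 0.5
#' keeps every entry positive so downstream capacity computation is
#' well-defined.
#'
#' @param calibration_scores Tibble as for [fit_kde_model()] (CCA scores), or
#'   a [gaze_feature_table()] tibble (columns `gx`, `gy`) for the gaze model
#'   family.
#' @param smoothing Laplace pseudo-count added to every cell. Default 0.5.
#' @param bw_floor Bandwidth floor passed to the model fits.
#' @return An object of class `ss_confusion`: a row-stochastic K x K matrix
#'   with attributes `n_trials` (per row) and `smoothing`.
#' @export
#' @examples
#' calib <- generate_ssvep_calibration(n_per_target = 6, duration_s = 1,
#'                                     snr = Inf, seed = 1)
#' calib |> cca_score_table(stimulus_set()) |> estimate_confusion(smoothing = 0)
estimate_confusion <- function(calibration_scores, smoothing = 0.5,
                               bw_floor = 0.01) {
  check_number(smoothing, "smoothing", min = 0)
  gaze_family <- all(c("gx", "gy") %in% names(calibration_scores))
  targets <- sort(unique(calibration_scores$intended_target))
  K <- length(targets)
  counts_in <- table(calibration_scores$intended_target)
  too_few <- names(counts_in)[counts_in < 5]
  if (length(too_few) > 0) {
    abort(paste0("insufficient calibration: fewer than 5 trials for ",
                 "target(s) ", paste(too_few, collapse = ", ")),
          class = "ss_insufficient_calibration")
  }
  counts <- matrix(0, K, K, dimnames = list(intended = targets,
                                            decoded = targets))
  n <- nrow(calibration_scores)
  for (i in seq_len(n)) {
    rest <- calibration_scores[-i, ]
    row <- calibration_scores[i, ]
    if (gaze_family) {
      if (!isTRUE(row$recognized)) next  # unrecognized trials are not forced
      model <- fit_gaze_model(rest, min_trials = 4L)
      lik <- class_likelihoods(model, c(row$gx, row$gy))
    } else {
      model <- fit_kde_model(rest, bw_floor = bw_floor, min_trials = 4L)
      obs <- as.numeric(row[, model$score_cols])
      lik <- class_likelihoods(model, obs)
    }
    decoded <- which.max(lik)
    intended <- match(row$intended_target, targets)
    counts[intended, decoded] <- counts[intended, decoded] + 1
  }
  new_confusion(counts, smoothing)
}

new_confusion <- function(counts, smoothing) {
  n_row <- rowSums(counts)
  sm <- counts + smoothing
  rs <- rowSums(sm)
  if (any(rs == 0)) {
    abort("confusion matrix has an empty row; increase `smoothing`",
          class = "ss_insufficient_calibration")
  }
  mat <- sm / rs
  structure(mat, n_trials = n_row, smoothing = smoothing,
            class = c("ss_confusion", "matrix"))
}

#' Validate / coerce a row-stochastic confusion matrix
#'
#' @param x A square numeric matrix whose rows sum to 1 (tolerance 1e-9).
#' @return An `ss_confusion` object.
#' @export
as_confusion <- function(x) {
  if (inherits(x, "ss_confusion")) return(x)
  x <- as.matrix(x)
  if (nrow(x) != ncol(x) || any(x < 0)) {
    stop_invalid("confusion matrix must be square and nonnegative")
  }
  if (any(abs(rowSums(x) - 1) > 1e-9)) {
    stop_invalid("confusion matrix rows must sum to 1 (tolerance 1e-9)")
  }
  structure(x / rowSums(x), n_trials = rep(NA_integer_, nrow(x)),
            smoothing = NA_real_, class = c("ss_confusion", "matrix"))
}

#' @export
print.ss_confusion <- function(x, ...) {
  cat(sprintf("<ss_confusion> %d x %d (smoothing %s)\n", nrow(x), ncol(x),
              format(attr(x, "smoothing"))))
  print(round(unclass(x), 4))
  invisible(x)
}

# ---- model serialization ----------------------------------------------------

#' Save / load a fitted KDE model as JSON
#'
#' The model is stored exactly (fit points and bandwidths), so the reload
#' reproduces likelihoods without refitting.
#'
#' @param model An `ss_kde_model`.
#' @param path Output JSON path.
#' @return `path` invisibly; `read_kde_model()` returns the model.
#' @export
write_kde_model <- function(model, path) {
  doc <- list(
    type = "ss_kde_model",
    targets = model$targets,
    score_cols = model$score_cols,
    n_per_target = model$n_per_target,
    bw_floor = model$bw_floor,
    densities = lapply(model$densities, function(dens_t) {
      lapply(dens_t, function(d) list(x = d$x, bandwidth = d$bandwidth))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kde_model
#' @export
read_kde_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  densities <- lapply(doc$densities, function(dens_t) {
    lapply(dens_t, function(d) {
      kde_1d(as.numeric(d$x), bandwidth = d$bandwidth)
    })
  })
  structure(
    list(densities = densities, targets = doc$targets,
         score_cols = doc$score_cols,
         n_per_target = doc$n_per_target, bw_floor = doc$bw_floor),
    class = "ss_kde_model"
  )
}
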