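#' Uniform posterior over the speller alphabet
#'
#' Every character selection starts from a uniform prior; conditioning on
#' previously typed text is exposed via the `prior` argument of
#' [run_selection()] but defaults off.
#'
#' @param alphabet Character vector, default [speller_alphabet()].
#' @return An `ss_posterior`: named probability vector with attributes
#'   `query_count` and `unrecognized_count` (both 0).
#' @export
uniform_posterior <- function(alphabet = speller_alphabet()) {
  new_posterior(stats::setNames(rep(1 / length(alphabet), length(alphabet)),
                                alphabet))
}

new_posterior <- function(p, query_count = 0L, unrecognized_count = 0L) {
  structure(p / sum(p), query_count = as.integer(query_count),
            unrecognized_count = as.integer(unrecognized_count),
            class = "ss_posterior")
}

#' @export
print.ss_posterior <- function(x, ...) {
  top <- sort(unclass(x), decreasing = TRUE)[seq_len(min(5, length(x)))]
  cat(sprintf("<ss_posterior> %d characters, %d queries (%d unrecognized)\n",
              length(x), attr(x, "query_count"),
              attr(x, "unrecognized_count")))
  cat("  top:", paste(sprintf("%s=%.3f", names(top), top), collapse = " "),
      "\n")
  invisible(x)
}

# Mutual information (bits) between intended and decoded box when `assignment`
# maps characters to boxes, the source is `posterior` and the channel is the
# confusion matrix.  Unassigned characters (NA) are ignored and the assigned
# mass renormalised.
partition_information <- function(assignment, posterior, confusion,
                                  n_boxes = nrow(confusion)) {
  p_box <- vapply(seq_len(n_boxes), function(b) {
    sum(posterior[which(assignment == b)])
  }, numeric(1))
  s <- sum(p_box)
  if (s <= 0) return(0)
  mutual_information_bits(p_box / s, unclass(confusion))
}

#' Information-optimal assignment of characters to boxes
#'
#' Finds an assignment of the alphabet to the `n_boxes` boxes that
#' (heuristically) maximises the expected information per query,
#' I(intended box; decoded box), where the intended-box distribution is the
#' current posterior aggregated by the assignment and the channel is the
#' user's confusion matrix.  Small instances (at most 65536 possible
#' assignments) are solved exactly by vectorised enumeration; for the full
#' 28-character alphabet the search is a greedy seeding pass (characters in
#' decreasing posterior order, each placed in the box giving the largest
#' partial-assignment information) followed by hill-climbing over
#' single-character moves, pairwise box swaps and pair co-moves to a local
#' optimum.  The procedure is deterministic; all ties break toward the
#' earlier box and the alphabet order.
#'
#' @param posterior An `ss_posterior` (or named probability vector).
#' @param confusion K x K row-stochastic [as_confusion()] matrix with
#'   K = `n_boxes`.
#' @param n_boxes Number of boxes, default 4.
#' @return An `ss_partition`: named integer vector (box index per character)
#'   with attribute `expected_information_bits`.
#' @export
#' @examples
#' optimize_partition(uniform_posterior(), diag(4))
optimize_partition <- function(posterior, confusion, n_boxes = 4L) {
  confusion <- as_confusion(confusion)
  if (nrow(confusion) != n_boxes) {
    stop_invalid("`n_boxes` must equal the confusion matrix dimension")
  }
  p <- unclass(posterior)
  chars <- names(p)
  n <- length(p)
  W <- unclass(confusion)
  # the objective depends on the assignment only through per-box posterior
  # mass: I = H(decoded) - sum_b P(box b) H(confusion row b)
  rowH <- apply(W, 1, entropy_bits)
  mi_pbox <- function(p_box) {
    s <- sum(p_box)
    if (s <= 0) return(0)
    pb <- p_box / s
    out <- as.numeric(pb %*% W)
    entropy_bits(out) - sum(pb * rowH)
  }
  # small alphabets: exact vectorised enumeration of every assignment
  if (n_boxes^n <= 65536) {
    ids <- 0:(n_boxes^n - 1)
    A <- matrix(0L, length(ids), n)
    for (j in seq_len(n)) {
      A[, j] <- (ids %/% n_boxes^(n - j)) %% n_boxes + 1L
    }
    Pbox <- vapply(seq_len(n_boxes), function(b) {
      as.numeric((A == b) %*% p)
    }, numeric(length(ids)))
    s <- rowSums(Pbox)
    Pn <- Pbox / ifelse(s > 0, s, 1)
    out <- Pn %*% W
    info <- -rowSums(xlog2x(out)) - as.numeric(Pn %*% rowH)
    info[s <= 0] <- 0
    best <- which(info >= max(info) - 1e-12)[1]  # lex-first tie-break
    return(structure(stats::setNames(A[best, ], chars),
                     expected_information_bits = max(info[best], 0),
                     n_boxes = as.integer(n_boxes),
                     class = "ss_partition"))
  }
  # greedy seeding: heaviest characters first, ties by alphabet order
  ord <- order(-p, seq_len(n))
  assignment <- rep(NA_integer_, n)
  p_box <- numeric(n_boxes)
  for (i in ord) {
    best_box <- 1L
    best_info <- -Inf
    for (b in seq_len(n_boxes)) {
      cand <- p_box
      cand[b] <- cand[b] + p[i]
      info <- mi_pbox(cand)
      if (info > best_info + 1e-12) {
        best_info <- info
        best_box <- b
      }
    }
    assignment[i] <- best_box
    p_box[best_box] <- p_box[best_box] + p[i]
  }
  current <- mi_pbox(p_box)
  # hill-climbing: single moves, then pair swaps, until no strict improvement
  repeat {
    improved <- FALSE
    for (i in seq_len(n)) {
      if (p[i] == 0) next  # massless characters cannot change the objective
      a <- assignment[i]
      for (b in seq_len(n_boxes)) {
        if (b == a) next
        cand <- p_box
        cand[a] <- cand[a] - p[i]
        cand[b] <- cand[b] + p[i]
        info <- mi_pbox(cand)
        if (info > current + 1e-12) {
          assignment[i] <- b
          p_box <- cand
          a <- b
          current <- info
          improved <- TRUE
        }
      }
    }
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (assignment[i] == assignment[j] || p[i] == p[j]) next
        a <- assignment[i]; b <- assignment[j]
        cand <- p_box
        cand[a] <- cand[a] + p[j] - p[i]
        cand[b] <- cand[b] + p[i] - p[j]
        info <- mi_pbox(cand)
        if (info > current + 1e-12) {
          assignment[c(i, j)] <- c(b, a)
          p_box <- cand
          current <- info
          improved <- TRUE
        }
      }
    }
    if (improved) next
    # escape pass: joint move of a character pair into one box, needed when
    # no single move or swap improves but a coordinated move does
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (p[i] == 0 && p[j] == 0) next
        a <- assignment[i]; b <- assignment[j]
        for (d in seq_len(n_boxes)) {
          if (d == a && d == b) next
          cand <- p_box
          cand[a] <- cand[a] - p[i]
          cand[b] <- cand[b] - p[j]
          cand[d] <- cand[d] + p[i] + p[j]
          info <- mi_pbox(cand)
          if (info > current + 1e-12) {
            assignment[c(i, j)] <- d
            p_box <- cand
            a <- d
            b <- d
            current <- info
            improved <- TRUE
          }
        }
      }
    }
    if (!improved) break
  }
  structure(stats::setNames(assignment, chars),
            expected_information_bits = current,
            n_boxes = as.integer(n_boxes),
            class = "ss_partition")
}

#' @export
print.ss_partition <- function(x, ...) {
  cat(sprintf("<ss_partition> %d characters -> %d boxes (%.4f bits expected)\n",
              length(x), attr(x, "n_boxes"),
              attr(x, "expected_information_bits")))
  for (b in seq_len(attr(x, "n_boxes"))) {
    cat(sprintf("  box %d: %s\n", b,
                paste(names(x)[unclass(x) == b], collapse = "")))
  }
  invisible(x)
}

#' Construct query evidence from per-box likelihoods
#'
#' Applies the recognition criterion: evidence is recognized when the
#' largest normalised box likelihood is at least `min_max_likelihood`
#' (default 0.3) and the ratio of largest to second largest raw likelihood
#' is at least `min_ratio` (default 1.05).  Unrecognized evidence does not
#' update the posterior.
#'
#' @param likelihoods Nonnegative per-box likelihood vector.
#' @param duration_s Trial (stimulation) duration of this query in seconds.
#' @param recognized Override the recognition criterion (logical), e.g. to
#'   emulate a decoder declaring input unusable.
#' @param min_max_likelihood,min_ratio Recognition criterion parameters.
#' @return An `ss_query_evidence` list.
#' @export
query_evidence <- function(likelihoods, duration_s = 2,
                           recognized = NULL,
                           min_max_likelihood = 0.3, min_ratio = 1.05) {
  likelihoods <- as.numeric(likelihoods)
  if (any(likelihoods < 0) || anyNA(likelihoods)) {
    stop_invalid("`likelihoods` must be nonnegative")
  }
  if (is.null(recognized)) {
    tot <- sum(likelihoods)
    if (tot == 0) {
      recognized <- FALSE
    } else {
      srt <- sort(likelihoods, decreasing = TRUE)
      recognized <- (srt[1] / tot) >= min_max_likelihood &&
        (srt[2] == 0 || srt[1] / srt[2] >= min_ratio)
    }
  }
  structure(list(likelihoods = likelihoods, recognized = isTRUE(recognized),
                 duration_s = duration_s),
            class = "ss_query_evidence")
}

#' Recursive Bayesian posterior update from one query
#'
#' Multiplies each character's posterior probability by the likelihood of
#' the box it was assigned to and renormalises.  Unrecognized evidence
#' leaves the probabilities unchanged and increments the unrecognized
#' counter instead of the query counter.  Computation is in log space so
#' long query sequences cannot underflow.
#'
#' @param posterior An `ss_posterior`.
#' @param partition An `ss_partition` over the same alphabet.
#' @param evidence An [query_evidence()].
#' @return The updated `ss_posterior`.
#' @export
bayes_update <- function(posterior, partition, evidence) {
  if (!identical(names(posterior), names(partition))) {
    stop_invalid("posterior and partition must cover the same alphabet")
  }
  qc <- attr(posterior, "query_count")
  uc <- attr(posterior, "unrecognized_count")
  if (!evidence$recognized) {
    return(new_posterior(unclass(posterior), qc, uc + 1L))
  }
  lik <- evidence$likelihoods
  if (all(lik == 0)) {
    abort("degenerate evidence: all box likelihoods are zero",
          class = "ss_degenerate_evidence")
  }
  log_post <- log(unclass(posterior)) + log(lik[unclass(partition)])
  finite <- is.finite(log_post)
  if (!any(finite)) {
    abort("degenerate evidence: posterior support has zero likelihood",
          class = "ss_degenerate_evidence")
  }
  m <- max(log_post[finite])
  p <- ifelse(finite, exp(log_post - m), 0)
  new_posterior(stats::setNames(p, names(posterior)), qc + 1L, uc)
}

#' Threshold-based character selection
#'
#' Returns the argmax character if and only if its posterior probability
#' strictly exceeds the confidence threshold (85% by default); otherwise
#' `NA`, meaning another query is required.  At exactly the threshold no
#' selection is made.
#'
#' @param posterior An `ss_posterior`.
#' @param threshold Confidence threshold, default 0.85.
#' @return A single character, or `NA_character_` when no character has
#'   cleared the threshold.
#' @export
select_character <- function(posterior, threshold = 0.85) {
  i <- which.max(posterior)
  if (posterior[[i]] > threshold) names(posterior)[i] else NA_character_
}

#' Run one character selection through the shuffle loop
#'
#' Repeats optimise-partition / present-query / update until one character's
#' posterior strictly exceeds the threshold, or a stop rule fires.  The user
#' is a function `user(intended_char, partition)` returning
#' [query_evidence()] (see [make_deterministic_user()],
#' [make_noisy_user()], [make_bci_user()]).  Simulated elapsed time counts
#' the 5 s initial alphabetical display, each query's trial duration, and
#' the 2 s re-shuffle pause between consecutive queries.
#'
#' @param intended_char The character the simulated user is trying to type.
#' @param user User-model function.
#' @param confusion The user's `ss_confusion` matrix (drives partitioning).
#' @param prior Starting posterior; default [uniform_posterior()].
#' @param threshold Selection threshold, default 0.85 (strict).
#' @param max_queries Abort (with a forced argmax decision) after this many
#'   queries. Default 30.
#' @param unrecognized_limit Abort after this many consecutive unrecognized
#'   queries. Default 10.
#' @param initial_display_s,pause_s Display timing constants (5 s, 2 s).
#' @return A list: `character` (selected, forced, or `NA` on unrecognized
#'   abort), `reason` (`"selected"`, `"max-queries"`,
#'   `"unrecognized-input"`), `forced`, `n_queries`, `n_unrecognized`,
#'   `elapsed_s`, `posterior`.
#' @export
run_selection <- function(intended_char, user, confusion,
                          prior = uniform_posterior(),
                          threshold = 0.85, max_queries = 30L,
                          unrecognized_limit = 10L,
                          initial_display_s = 5, pause_s = 2) {
  posterior <- prior
  elapsed <- initial_display_s
  n_queries <- 0L
  consecutive_unrecognized <- 0L
  repeat {
    partition <- optimize_partition(posterior, confusion,
                                    n_boxes = nrow(confusion))
    evidence <- user(intended_char, partition)
    if (n_queries > 0L) elapsed <- elapsed + pause_s
    n_queries <- n_queries + 1L
    elapsed <- elapsed + evidence$duration_s
    posterior <- bayes_update(posterior, partition, evidence)
    if (evidence$recognized) {
      consecutive_unrecognized <- 0L
      sel <- select_character(posterior, threshold)
      if (!is.na(sel)) {
        return(list(character = sel, reason = "selected", forced = FALSE,
                    n_queries = n_queries,
                    n_unrecognized = attr(posterior, "unrecognized_count"),
                    elapsed_s = elapsed, posterior = posterior))
      }
    } else {
      consecutive_unrecognized <- consecutive_unrecognized + 1L
      if (consecutive_unrecognized >= unrecognized_limit) {
        return(list(character = NA_character_,
                    reason = "unrecognized-input", forced = FALSE,
                    n_queries = n_queries,
                    n_unrecognized = attr(posterior, "unrecognized_count"),
                    elapsed_s = elapsed, posterior = posterior))
      }
    }
    if (n_queries >= max_queries) {
      return(list(character = names(posterior)[which.max(posterior)],
                  reason = "max-queries", forced = TRUE,
                  n_queries = n_queries,
                  n_unrecognized = attr(posterior, "unrecognized_count"),
                  elapsed_s = elapsed, posterior = posterior))
    }
  }
}

# ---- simulated user models --------------------------------------------------

#' Simulated users for the shuffle loop
#'
#' Each constructor returns a function `user(intended_char, partition)`
#' producing [query_evidence()] for one query.
#'
#' * `make_deterministic_user()` always responds with `box_likelihoods[1]`
#'   on the box holding the intended character and the remaining values on
#'   the other boxes, in box order.
#' * `make_noisy_user()` responds on the correct box with probability
#'   `accuracy` and on a uniformly chosen other box otherwise, with
#'   likelihood `strength` on the responded box and 1 elsewhere.
#' * `make_unrecognized_user()` always produces unrecognized evidence.
#' * `make_bci_user()` closes the full loop: it generates a synthetic SSVEP
#'   trial for the box holding the intended character, extracts CCA scores,
#'   and returns the fitted KDE model's class likelihoods as the per-box
#'   evidence.
#'
#' @param box_likelihoods Length-4 likelihoods, correct box first.
#' @param duration_s Trial duration per query.
#' @param accuracy Probability of responding on the correct box.
#' @param strength Likelihood of the responded box relative to the others.
#' @param seed Integer seed (stateful closures derive one sub-seed per call).
#' @param model Fitted `ss_kde_model` used to decode generated trials.
#' @param stimulus_set,snr,rate_hz Passed to [generate_ssvep_trial()].
#' @param trial_length_s Stimulation duration per query (e.g. the chosen
#'   trial length).
#' @return A user-model function.
#' @name user_models
NULL

#' @rdname user_models
#' @export
make_deterministic_user <- function(box_likelihoods = c(0.85, 0.05, 0.05, 0.05),
                                    duration_s = 2) {
  force(box_likelihoods)
  function(intended_char, partition) {
    correct_box <- unclass(partition)[[intended_char]]
    lik <- numeric(length(box_likelihoods))
    lik[correct_box] <- box_likelihoods[1]
    lik[-correct_box] <- box_likelihoods[-1]
    query_evidence(lik, duration_s = duration_s)
  }
}

#' @rdname user_models
#' @export
make_noisy_user <- function(accuracy, strength = 19, duration_s = 2, seed) {
  if (missing(seed)) stop_invalid("`seed` is required.")
  counter <- 0L
  function(intended_char, partition) {
    counter <<- counter + 1L
    n_boxes <- attr(partition, "n_boxes")
    correct_box <- unclass(partition)[[intended_char]]
    with_seed((seed * 131071L + counter) %% .Machine$integer.max, {
      responded <- if (runif(1) < accuracy) {
        correct_box
      } else {
        sample(setdiff(seq_len(n_boxes), correct_box), 1)
      }
      lik <- rep(1, n_boxes)
      lik[responded] <- strength
      query_evidence(lik, duration_s = duration_s)
    })
  }
}

#' @rdname user_models
#' @export
make_unrecognized_user <- function(duration_s = 2) {
  function(intended_char, partition) {
    n_boxes <- attr(partition, "n_boxes")
    query_evidence(rep(1, n_boxes), duration_s = duration_s,
                   recognized = FALSE)
  }
}

#' @rdname user_models
#' @export
make_bci_user <- function(model, stimulus_set = shufflespeller::stimulus_set(),
                          snr = 1, trial_length_s = 2, rate_hz = 256, seed) {
  if (missing(seed)) stop_invalid("`seed` is required.")
  counter <- 0L
  bank <- build_reference_bank(stimulus_set, trial_length_s, rate_hz)
  function(intended_char, partition) {
    counter <<- counter + 1L
    correct_box <- unclass(partition)[[intended_char]]
    trial_seed <- as.integer((seed * 65537L + counter * 97L) %%
                               .Machine$integer.max)
    seg <- generate_ssvep_trial(correct_box, trial_length_s, snr,
                                stimulus_set, rate_hz, seed = trial_seed)
    scores <- cca_scores(seg, bank)
    query_evidence(class_likelihoods(model, as.numeric(scores)),
                   duration_s = trial_length_s)
  }
}
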