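#' Bundled five-letter word pool
#'
#' Sixty-five common five-letter English words used to build copy-spelling
#' word lists.  This is a synthetic stand-in pool of comparable common
#' words; word identity does not affect any computation.
#'
#' @return Character vector of 65 unique uppercase five-letter words.
#' @export
word_pool <- function() {
  c("ABOUT", "AFTER", "AGAIN", "APPLE", "BEACH", "BEGIN", "BLACK", "BREAD",
    "BROWN", "CHAIR", "CHILD", "CLEAN", "CLOCK", "CLOUD", "DANCE", "DREAM",
    "DRINK", "EARLY", "EARTH", "FIELD", "FIRST", "FLOOR", "FRESH", "FRONT",
    "FRUIT", "GLASS", "GREAT", "GREEN", "HAPPY", "HEART", "HORSE", "HOUSE",
    "LARGE", "LAUGH", "LEARN", "LIGHT", "LUNCH", "MONEY", "MONTH", "MUSIC",
    "NIGHT", "NORTH", "OCEAN", "PAPER", "PARTY", "PEACE", "PLANT", "PLATE",
    "POINT", "QUIET", "RADIO", "RIVER", "ROUND", "SHARE", "SHIRT", "SLEEP",
    "SMALL", "SMILE", "SOUTH", "STAND", "START", "STONE", "STORY", "SWEET",
    "TABLE")
}

#' Sample copy-spelling word lists
#'
#' Draws `n_lists` lists of five distinct words from [word_pool()]; lists
#' are pairwise distinct (as unordered sets).  A session uses one list;
#' across a study, lists are consumed without replacement.
#'
#' @param n_lists Number of lists, default 26.
#' @param seed Integer seed.
#' @return A list of character vectors of length 5.
#' @export
sample_word_lists <- function(n_lists = 26, seed) {
  if (missing(seed)) stop_invalid("`seed` is required.")
  pool <- word_pool()
  with_seed(seed, {
    lists <- list()
    keys <- character(0)
    tries <- 0L
    while (length(lists) < n_lists) {
      tries <- tries + 1L
      if (tries > 10000L) stop_invalid("could not sample distinct word lists")
      w <- sample(pool, 5)
      key <- paste(sort(w), collapse = ",")
      if (!(key %in% keys)) {
        keys <- c(keys, key)
        lists[[length(lists) + 1L]] <- w
      }
    }
    lists
  })
}

#' Next intended character in a copy-spelling task
#'
#' If the typed string is a prefix of the target word, the intended
#' character is the next letter; any typing error makes backspace (`"<"`)
#' the intended character until the error is deleted.  A fully typed word
#' returns `NA` (word complete).
#'
#' @param typed_string Characters typed so far (uppercase speller symbols).
#' @param target_word The word being copied.
#' @return A single character, or `NA_character_` when the word is complete.
#' @export
#' @examples
#' intended_target("", "HOUSE")     # "H"
#' intended_target("HOX", "HOUSE")  # "<"
intended_target <- function(typed_string, target_word) {
  if (typed_string == target_word) return(NA_character_)
  if (nchar(typed_string) < nchar(target_word) &&
      substr(target_word, 1, nchar(typed_string)) == typed_string) {
    return(substr(target_word, nchar(typed_string) + 1,
                  nchar(typed_string) + 1))
  }
  "<"
}

#' Categorise one selection
#'
#' A selection matching the intended character is a correct letter
#' selection, or a correct backspace selection when the intended character
#' is backspace (deleting an erroneous character counts as correct);
#' anything else is incorrect.  Backspace with nothing typed (and nothing
#' to delete) is incorrect.
#'
#' @param selected The character actually selected.
#' @param typed_string_before Typed string before this selection.
#' @param target_word Target word.
#' @return `"correct_letter"`, `"correct_backspace"` or `"incorrect"`.
#' @export
categorize_selection <- function(selected, typed_string_before, target_word) {
  intended <- intended_target(typed_string_before, target_word)
  if (is.na(intended)) return("incorrect")
  if (identical(selected, intended)) {
    if (intended == "<") "correct_backspace" else "correct_letter"
  } else {
    "incorrect"
  }
}

apply_selection <- function(typed, selected) {
  if (selected == "<") {
    if (nchar(typed) > 0) substr(typed, 1, nchar(typed) - 1) else typed
  } else {
    paste0(typed, selected)
  }
}

#' Session configuration
#'
#' @param condition One of `"C1.2"`, `"C2.5"`, `"SSET"`, `"SSBCI"`.
#' @param dwell_s Dwell-click duration for the dwell conditions (1.2 s for
#'   C1.2, 2.5 s for C2.5 by default).
#' @param session_cap_s Session wall cap, default 1200 s (20 min).
#' @param early_stop_s Terminate if no correct selection by this time,
#'   default 300 s (5 min).
#' @param consecutive_error_limit Word advances after this many consecutive
#'   incorrect selections, default 4.
#' @param threshold,max_queries,unrecognized_limit Shuffle-engine settings
#'   (see [run_selection()]).
#' @param initial_display_s,pause_s Shuffle display timing (5 s, 2 s).
#' @param attempt_cap_s Dwell conditions: a single box-selection attempt is
#'   abandoned (time still elapses) after this long without a dwell click.
#' @param seed Integer seed for the session's own randomness.
#' @return An `ss_session_config` list.
#' @export
session_config <- function(condition, dwell_s = NULL,
                           session_cap_s = 1200, early_stop_s = 300,
                           consecutive_error_limit = 4L,
                           threshold = 0.85, max_queries = 30L,
                           unrecognized_limit = 10L,
                           initial_display_s = 5, pause_s = 2,
                           attempt_cap_s = 30, seed = 1L) {
  conditions <- c("C1.2", "C2.5", "SSET", "SSBCI")
  if (!(is.character(condition) && length(condition) == 1L &&
        condition %in% conditions)) {
    stop_invalid(paste("`condition` must be one of:",
                       paste(conditions, collapse = ", ")))
  }
  if (is.null(dwell_s)) {
    dwell_s <- switch(condition, "C1.2" = 1.2, "C2.5" = 2.5, NA_real_)
  }
  structure(
    list(condition = condition, dwell_s = dwell_s,
         session_cap_s = session_cap_s, early_stop_s = early_stop_s,
         consecutive_error_limit = as.integer(consecutive_error_limit),
         threshold = threshold, max_queries = as.integer(max_queries),
         unrecognized_limit = as.integer(unrecognized_limit),
         initial_display_s = initial_display_s, pause_s = pause_s,
         attempt_cap_s = attempt_cap_s, seed = as.integer(seed)),
    class = "ss_session_config"
  )
}

# Shared copy-spelling loop.  `select_fn(intended_char, budget_s)` performs
# one selection attempt and returns list(character (NA if none), elapsed_s,
# n_queries, reason).  Stop-rule precedence: session cap, early stop, word
# advancement.
copy_session_loop <- function(config, select_fn, word_list) {
  events <- list()
  clock <- 0
  n_correct <- 0L
  word_idx <- 1L
  typed <- ""
  consecutive_incorrect <- 0L
  add_event <- function(kind, character = NA_character_,
                        category = NA_character_, n_queries = NA_integer_,
                        duration_s = NA_real_, reason = NA_character_,
                        word = NA_character_, typed_before = NA_character_) {
    events[[length(events) + 1L]] <<- tibble::tibble(
      timestamp_s = clock, event = kind, character = character,
      category = category, n_queries = n_queries, duration_s = duration_s,
      reason = reason, word = word, typed_before = typed_before
    )
  }
  finish <- function(reason) {
    add_event("stop", reason = reason)
    log <- dplyr::bind_rows(events)
    structure(log, class = c("ss_session_log", class(log)),
              condition = config$condition,
              active_typing_time_s = clock,
              word_list = word_list)
  }
  advance_word <- function(reason) {
    add_event("word_advance", reason = reason, word = word_list[word_idx])
    word_idx <<- word_idx + 1L
    typed <<- ""
    consecutive_incorrect <<- 0L
  }
  repeat {
    if (word_idx > length(word_list)) return(finish("complete"))
    target <- word_list[word_idx]
    intended <- intended_target(typed, target)
    if (is.na(intended)) {
      advance_word("word-complete")
      next
    }
    budget <- config$session_cap_s - clock
    if (n_correct == 0L) budget <- min(budget, config$early_stop_s - clock)
    res <- select_fn(intended, budget)
    typed_before <- typed
    clock <- clock + res$elapsed_s
    if (!is.na(res$character)) {
      category <- categorize_selection(res$character, typed_before, target)
      typed <- apply_selection(typed, res$character)
      add_event("selection", character = res$character, category = category,
                n_queries = res$n_queries, duration_s = res$elapsed_s,
                word = target, typed_before = typed_before)
      if (category == "incorrect") {
        consecutive_incorrect <- consecutive_incorrect + 1L
      } else {
        consecutive_incorrect <- 0L
        n_correct <- n_correct + 1L
      }
    }
    # stop rules, in precedence order
    if (clock >= config$session_cap_s) return(finish("session-cap"))
    if (clock >= config$early_stop_s && n_correct == 0L) {
      return(finish("early-stop"))
    }
    if (!is.na(res$character) && consecutive_incorrect >=
        config$consecutive_error_limit) {
      advance_word("consecutive-errors")
      next
    }
    if (is.na(res$character) && identical(res$reason, "unrecognized-input")) {
      advance_word("unrecognized")
      next
    }
    if (typed == target) {
      advance_word("word-complete")
    }
  }
}

#' Run a copy-spelling session
#'
#' Simulates one session of the copy-spelling protocol: five words typed
#' character by character, error correction via backspace, word advancement
#' after `consecutive_error_limit` consecutive errors or persistent
#' unrecognized input, early termination at `early_stop_s` if nothing
#' correct has been typed, and a hard cap at `session_cap_s`.  For the
#' shuffle conditions (`SSET`, `SSBCI`) selections run through
#' [run_selection()] with the supplied user model and confusion matrix; for
#' the dwell conditions (`C1.2`, `C2.5`) they run through
#' [simulate_dwell_speller()]'s three-step hierarchy.
#'
#' @param config An [session_config()].
#' @param user For shuffle conditions, a user-model function (see
#'   [user_models]); for dwell conditions, a list
#'   `list(scatter_deg = , dropout_rate = )` describing the gaze model.
#' @param word_list Character vector of five-letter target words.
#' @param confusion `ss_confusion` matrix (shuffle conditions only).
#' @param layout [screen_layout()] (dwell conditions only).
#' @return An `ss_session_log`: a tibble of timestamped events (`selection`,
#'   `word_advance`, `stop`) with attributes `condition`,
#'   `active_typing_time_s` and `word_list`.
#' @export
run_copy_session <- function(config, user, word_list, confusion = NULL,
                             layout = screen_layout()) {
  if (!inherits(config, "ss_session_config")) {
    stop_invalid("`config` must come from session_config()")
  }
  if (config$condition %in% c("SSET", "SSBCI")) {
    if (is.null(confusion)) {
      stop_invalid("shuffle conditions need a `confusion` matrix")
    }
    select_fn <- function(intended, budget) {
      res <- run_selection(
        intended, user, confusion,
        threshold = config$threshold,
        max_queries = config$max_queries,
        unrecognized_limit = config$unrecognized_limit,
        initial_display_s = config$initial_display_s,
        pause_s = config$pause_s
      )
      list(character = res$character, elapsed_s = res$elapsed_s,
           n_queries = res$n_queries, reason = res$reason)
    }
    copy_session_loop(config, select_fn, word_list)
  } else {
    simulate_dwell_speller(config, user, word_list, layout)
  }
}

# ---- dwell-based three-step speller -----------------------------------------

# Fixed three-level grouping: alphabetical blocks of <= 7 assigned to the
# top, right, bottom, left boxes; level 2 splits a block into sub-groups of
# <= 2; level 3 shows at most one character per box.
dwell_groups <- function(alphabet = speller_alphabet()) {
  box_order <- c(1L, 4L, 2L, 3L)  # top, right, bottom, left
  split_into <- function(chars, max_groups = 4L) {
    n <- length(chars)
    size <- ceiling(n / max_groups)
    split(chars, ceiling(seq_along(chars) / size))
  }
  level1 <- split_into(alphabet)
  list(level1 = level1, box_order = box_order, split_into = split_into)
}

# One dwell attempt: stream gaze samples around the intended box centre and
# return the first box accumulating `dwell_s` of continuous gaze, or NA if
# the attempt cap elapses first.  Time advances by one sample period per
# gaze sample.
dwell_attempt <- function(intended_box, layout, scatter_deg, dwell_s,
                          attempt_cap_s, rate_hz = 60, seed,
                          go_back_box = NULL) {
  n_max <- ceiling(attempt_cap_s * rate_hz)
  need <- ceiling(dwell_s * rate_hz)
  ctr <- if (is.null(go_back_box)) box_center(layout, intended_box) else
    go_back_center(layout)
  with_seed(seed, {
    x <- ctr[1] + rnorm(n_max, sd = scatter_deg)
    y <- ctr[2] + rnorm(n_max, sd = scatter_deg)
    boxes <- point_in_box(layout, x, y)
    if (!is.null(go_back_box)) {
      in_gb <- abs(x - ctr[1]) <= 2 & abs(y - ctr[2]) <= 2
      boxes[in_gb] <- go_back_box
    }
    run_box <- NA_integer_
    run_len <- 0L
    for (i in seq_len(n_max)) {
      b <- boxes[i]
      if (!is.na(b) && !is.na(run_box) && b == run_box) {
        run_len <- run_len + 1L
      } else {
        run_box <- b
        run_len <- if (is.na(b)) 0L else 1L
      }
      if (!is.na(run_box) && run_len >= need) {
        return(list(box = run_box, elapsed_s = i / rate_hz))
      }
    }
    list(box = NA_integer_, elapsed_s = n_max / rate_hz)
  })
}

go_back_center <- function(layout) c(0, 0)  # small central "go back" target

#' Simulate a dwell-based three-step speller session
#'
#' The baseline conditions use a static keyboard in which each character
#' selection requires three successive box selections: the large
#' alphabetical group (A-G always in the top box, and so on), a small
#' sub-group of at most two characters, then the character itself.  A box
#' is selected when continuous gaze inside it accumulates `dwell_s`
#' (accumulation resets on leaving the box).  Selecting a wrong group is
#' corrected through a central "go back" target; selecting a wrong final
#' character types it.  The simulated user fixates the box containing the
#' intended character with isotropic gaze scatter.
#'
#' @inheritParams run_copy_session
#' @param gaze A list with `scatter_deg` (gaze scatter s.d. in degrees).
#' @return An `ss_session_log` (same schema as [run_copy_session()]).
#' @export
simulate_dwell_speller <- function(config, gaze, word_list,
                                   layout = screen_layout()) {
  if (!inherits(config, "ss_session_config")) {
    stop_invalid("`config` must come from session_config()")
  }
  if (!(config$dwell_s > 0)) stop_invalid("`dwell_s` must be positive")
  scatter <- gaze$scatter_deg %||% 0
  groups <- dwell_groups()
  counter <- 0L
  next_seed <- function() {
    counter <<- counter + 1L
    as.integer((config$seed * 48611L + counter * 293L) %%
                 .Machine$integer.max)
  }
  box_of <- function(grouping, char) {
    for (g in seq_along(grouping)) {
      if (char %in% grouping[[g]]) return(g)
    }
    NA_integer_
  }
  select_fn <- function(intended, budget) {
    elapsed <- 0
    n_dwells <- 0L
    grouping <- groups$level1
    level <- 1L
    repeat {
      if (elapsed >= budget) {
        return(list(character = NA_character_, elapsed_s = elapsed,
                    n_queries = n_dwells, reason = "timeout"))
      }
      g_int <- box_of(grouping, intended)
      # intended box on screen for this level (slot order top,right,bottom,left)
      slot_boxes <- groups$box_order[seq_along(grouping)]
      intended_box <- if (is.na(g_int)) NA_integer_ else slot_boxes[g_int]
      att <- dwell_attempt(intended_box, layout, scatter, config$dwell_s,
                           min(config$attempt_cap_s, budget - elapsed),
                           seed = next_seed())
      elapsed <- elapsed + att$elapsed_s
      if (is.na(att$box)) next  # no dwell click this attempt; time passed
      n_dwells <- n_dwells + 1L
      slot <- match(att$box, slot_boxes)
      if (is.na(slot)) next  # dwelled on an unused box; nothing happens
      chosen <- grouping[[slot]]
      if (level == 3L) {
        # third click types the character (right or wrong)
        return(list(character = chosen[1], elapsed_s = elapsed,
                    n_queries = n_dwells, reason = "selected"))
      }
      if (slot == g_int) {
        # correct group: descend one level
        grouping <- groups$split_into(chosen)
        level <- level + 1L
      } else {
        # wrong group: go back (a dwell on the central go-back target),
        # then retry this level from the top of the hierarchy
        gb <- dwell_attempt(NA_integer_, layout, scatter, config$dwell_s,
                            min(config$attempt_cap_s, budget - elapsed),
                            seed = next_seed(), go_back_box = 99L)
        elapsed <- elapsed + gb$elapsed_s
        grouping <- groups$level1
        level <- 1L
      }
    }
  }
  copy_session_loop(config, select_fn, word_list)
}

# ---- session log I/O --------------------------------------------------------

#' Write / read a session log as JSON Lines
#'
#' The first line is a header record (condition, active typing time, word
#' list); each following line is one event.
#'
#' @param log An `ss_session_log`.
#' @param path Output path.
#' @return `path` invisibly; `read_session_log()` returns the log.
#' @export
write_session_log <- function(log, path) {
  header <- list(type = "header",
                 condition = attr(log, "condition"),
                 active_typing_time_s = attr(log, "active_typing_time_s"),
                 word_list = attr(log, "word_list"))
  lines <- c(
    jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA, null = "null"),
    vapply(seq_len(nrow(log)), function(i) {
      as.character(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE,
                                    digits = NA, null = "null", na = "null"))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1])
  events <- dplyr::bind_rows(lapply(lines[-1], function(l) {
    rec <- jsonlite::fromJSON(l)
    rec[vapply(rec, is.null, logical(1))] <- NA
    tibble::as_tibble(rec)
  }))
  events$n_queries <- as.integer(events$n_queries)
  structure(events, class = c("ss_session_log", class(events)),
            condition = header$condition,
            active_typing_time_s = header$active_typing_time_s,
            word_list = header$word_list)
}

#' Replay a session log's selection categories
#'
#' Recomputes every selection's category from the event stream alone (typed
#' string reconstructed word by word) -- a consistency check that stored
#' categories are reachable from [intended_target()] /
#' [categorize_selection()].
#'
#' @param log An `ss_session_log`.
#' @return Character vector of recomputed categories, one per selection
#'   event, in order.
#' @export
replay_categories <- function(log) {
  sel <- log[log$event == "selection", ]
  vapply(seq_len(nrow(sel)), function(i) {
    categorize_selection(sel$character[i], sel$typed_before[i], sel$word[i])
  }, character(1))
}
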