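sym4 <- function(p) {
  m <- matrix((1 - p) / 3, 4, 4)
  diag(m) <- p
  m
}

test_that("intended_target follows copy-spelling error-correction rules", {
  expect_equal(intended_target("", "HOUSE"), "H")
  expect_equal(intended_target("HOU", "HOUSE"), "S")
  expect_equal(intended_target("HOX", "HOUSE"), "<")
  expect_equal(intended_target("HOUSEX", "HOUSE"), "<")
  expect_true(is.na(intended_target("HOUSE", "HOUSE")))
})

test_that("selections are categorised against the intended character", {
  expect_equal(categorize_selection("H", "", "HOUSE"), "correct_letter")
  expect_equal(categorize_selection("<", "HOX", "HOUSE"),
               "correct_backspace")
  expect_equal(categorize_selection("Q", "", "HOUSE"), "incorrect")
  # backspace with nothing typed deletes nothing and counts as incorrect
  expect_equal(categorize_selection("<", "", "HOUSE"), "incorrect")
})

test_that("a perfect user types five words as 25 correct letters", {
  words <- c("HOUSE", "APPLE", "BREAD", "CHAIR", "DANCE")
  cfg <- session_config("SSET", seed = 1)
  user <- make_deterministic_user(c(0.9, 0.04, 0.03, 0.03))
  log <- run_copy_session(cfg, user, words, confusion = sym4(0.95))
  sel <- log[log$event == "selection", ]
  expect_equal(nrow(sel), 25)
  expect_true(all(sel$category == "correct_letter"))
  expect_equal(sum(log$event == "word_advance"), 5)
  expect_equal(log$reason[log$event == "stop"], "complete")
})

test_that("four consecutive incorrect selections advance the word", {
  words <- c("HOUSE", "APPLE")
  cfg <- session_config("SSET", seed = 2, consecutive_error_limit = 4)
  # user who always produces evidence for box 1 regardless of intent:
  # selections are effectively unrelated to the target word
  bad_user <- function(intended_char, partition) {
    query_evidence(c(0.97, 0.01, 0.01, 0.01), duration_s = 2)
  }
  log <- run_copy_session(cfg, bad_user, words, confusion = sym4(0.95))
  sel <- log[log$event == "selection", ]
  adv <- which(log$event == "word_advance" &
                 log$reason == "consecutive-errors")
  expect_gte(length(adv), 1)
  # exactly 4 incorrect selections precede the first such advance
  first_adv_t <- log$timestamp_s[adv[1]]
  before <- sel[sel$timestamp_s <= first_adv_t, ]
  expect_equal(nrow(before), 4)
  expect_true(all(before$category == "incorrect"))
})

test_that("persistent unrecognized input advances the word", {
  cfg <- session_config("SSET", seed = 3, unrecognized_limit = 10,
                        early_stop_s = 1e6, session_cap_s = 1e6)
  log <- run_copy_session(cfg, make_unrecognized_user(), c("HOUSE", "APPLE"),
                          confusion = sym4(0.9))
  expect_true(all(log$reason[log$event == "word_advance"] == "unrecognized"))
  expect_equal(sum(log$event == "word_advance"), 2)
  expect_equal(sum(log$event == "selection"), 0)
})

test_that("early stop fires at 300 s with zero correct selections", {
  cfg <- session_config("SSET", seed = 4)
  bad_user <- function(intended_char, partition) {
    query_evidence(c(0.97, 0.01, 0.01, 0.01), duration_s = 2)
  }
  # words with no early-alphabet letters keep a box-1-biased user from
  # ever typing a correct character; enough words that word advancement
  # alone cannot finish the list before the 300 s checkpoint
  log <- run_copy_session(cfg, bad_user,
                          rep(c("ZZZZZ", "YYYYY"), 6),
                          confusion = sym4(0.95))
  stop_row <- log[log$event == "stop", ]
  expect_equal(stop_row$reason, "early-stop")
  expect_gte(stop_row$timestamp_s, 300)
  sel <- log[log$event == "selection", ]
  expect_true(all(sel$category == "incorrect"))
})

test_that("the 20-minute session cap fires with a slow but accurate user", {
  cfg <- session_config("SSET", seed = 5, session_cap_s = 1200)
  # ~59 s per selection (weak but consistent evidence), correct letters
  slow_user <- make_deterministic_user(c(0.30, 0.2333, 0.2333, 0.2334),
                                       duration_s = 2)
  words <- c("HOUSE", "APPLE", "BREAD", "CHAIR", "DANCE")
  log <- run_copy_session(cfg, slow_user, words, confusion = sym4(0.9))
  stop_row <- log[log$event == "stop", ]
  expect_equal(stop_row$reason, "session-cap")
  expect_gte(attr(log, "active_typing_time_s"), 1200)
})

test_that("replaying a log reproduces every stored category", {
  cfg <- session_config("SSET", seed = 6)
  user <- make_noisy_user(0.8, strength = 9, seed = 11)
  log <- run_copy_session(cfg, user, c("HOUSE", "APPLE"),
                          confusion = sym4(0.8))
  sel <- log[log$event == "selection", ]
  expect_gt(nrow(sel), 0)
  expect_equal(replay_categories(log), sel$category)
  # timestamps are nondecreasing and active time matches the durations
  expect_true(all(diff(log$timestamp_s) >= 0))
  expect_equal(attr(log, "active_typing_time_s"), sum(sel$duration_s))
})

test_that("session logs round-trip through JSON Lines", {
  cfg <- session_config("SSET", seed = 7)
  user <- make_deterministic_user()
  log <- run_copy_session(cfg, user, c("HOUSE"), confusion = sym4(0.9))
  path <- file.path(tempdir(), "log.jsonl")
  write_session_log(log, path)
  back <- read_session_log(path)
  expect_equal(attr(back, "condition"), attr(log, "condition"))
  expect_equal(attr(back, "active_typing_time_s"),
               attr(log, "active_typing_time_s"))
  expect_equal(back$category, log$category)
  expect_equal(replay_categories(back), replay_categories(log))
  expect_equal(as.numeric(glance(back)$accuracy_incl_backspace),
               as.numeric(glance(log)$accuracy_incl_backspace))
})

test_that("word lists are five-letter, unique, and sampled without repeats", {
  pool <- word_pool()
  expect_length(pool, 65)
  expect_true(all(nchar(pool) == 5))
  expect_true(all(grepl("^[A-Z]{5}$", pool)))
  expect_false(anyDuplicated(pool) > 0)
  lists <- sample_word_lists(26, seed = 1)
  expect_length(lists, 26)
  keys <- vapply(lists, function(w) paste(sort(w), collapse = ","),
                 character(1))
  expect_false(anyDuplicated(keys) > 0)
  expect_identical(sample_word_lists(26, seed = 1), lists)
})

test_that("dwell selection triggers at exactly the dwell duration", {
  cfg <- session_config("C1.2", seed = 8)
  log <- simulate_dwell_speller(cfg, list(scatter_deg = 0), "AB")
  sel <- log[log$event == "selection", ]
  expect_equal(sel$character, c("A", "B"))
  expect_true(all(sel$category == "correct_letter"))
  # three dwell clicks of exactly 1.2 s each per character
  expect_equal(sel$n_queries, c(3L, 3L))
  expect_equal(sel$duration_s, c(3.6, 3.6), tolerance = 1e-9)
})

test_that("gaze alternating between boxes never accumulates a dwell click", {
  # accumulation resets on exit: alternating 0.5 s halves below a 1.2 s
  # dwell never select
  layout <- screen_layout()
  centers <- layout$boxes
  n <- 60 * 10
  half <- 30  # samples per 0.5 s
  xs <- rep(c(rep(centers$cx[1], half), rep(centers$cx[2], half)), length.out = n)
  ys <- rep(c(rep(centers$cy[1], half), rep(centers$cy[2], half)), length.out = n)
  boxes <- shufflespeller:::point_in_box(layout, xs, ys)
  need <- ceiling(1.2 * 60)
  run_len <- 0L
  run_box <- NA_integer_
  clicked <- FALSE
  for (i in seq_along(boxes)) {
    b <- boxes[i]
    if (!is.na(b) && !is.na(run_box) && b == run_box) {
      run_len <- run_len + 1L
    } else {
      run_box <- b
      run_len <- if (is.na(b)) 0L else 1L
    }
    if (!is.na(run_box) && run_len >= need) clicked <- TRUE
  }
  expect_false(clicked)
})

test_that("hopeless gaze scatter produces a zero-correct early stop", {
  cfg <- session_config("C1.2", seed = 9, attempt_cap_s = 30)
  log <- simulate_dwell_speller(cfg, list(scatter_deg = 1e6),
                                c("HOUSE", "APPLE", "BREAD", "CHAIR",
                                  "DANCE"))
  sel <- log[log$event == "selection", ]
  expect_equal(sum(sel$category %in% c("correct_letter",
                                       "correct_backspace")), 0)
  expect_equal(log$reason[log$event == "stop"], "early-stop")
})

test_that("moderate gaze scatter still completes words in the C2.5 condition", {
  cfg <- session_config("C2.5", seed = 10)
  log <- simulate_dwell_speller(cfg, list(scatter_deg = 0.8), c("HOUSE"))
  m <- glance(log)
  expect_gte(m$n_correct_letters, 5)
})
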