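sym_channel <- function(K, p) {
  m <- matrix((1 - p) / (K - 1), K, K)
  diag(m) <- p
  m
}

named_posterior <- function(p, chars = LETTERS[seq_along(p)]) {
  shufflespeller:::new_posterior(stats::setNames(p, chars))
}

test_that("partition optimiser matches exhaustive search on 6 chars x 2 boxes", {
  W <- sym_channel(2, 0.9)
  set.seed(1)
  p <- named_posterior(as.numeric(stats::rexp(6)))
  part <- optimize_partition(p, W, n_boxes = 2)
  best <- oracle_best_partition_info(unclass(p), W, 2)
  expect_equal(attr(part, "expected_information_bits"), best,
               tolerance = 1e-10)
})

test_that("partition optimiser reaches >= 99% of the optimum on random instances", {
  for (s in 1:50) {
    set.seed(s)
    n_chars <- sample(4:8, 1)
    n_boxes <- sample(2:3, 1)
    W <- random_stochastic(n_boxes, seed = 1000 + s)
    # sharpen toward a usable channel so the optimum is not trivially 0
    W <- 0.3 * W + 0.7 * diag(n_boxes)
    p <- named_posterior(as.numeric(stats::rexp(n_chars)))
    part <- optimize_partition(p, W, n_boxes = n_boxes)
    best <- oracle_best_partition_info(unclass(p), W, n_boxes)
    expect_gte(attr(part, "expected_information_bits"), 0.99 * best - 1e-12)
  }
})

test_that("degenerate partitions are handled deterministically", {
  W <- diag(4)
  point <- named_posterior(c(1, 0, 0, 0, 0, 0))
  part <- optimize_partition(point, W)
  expect_equal(attr(part, "expected_information_bits"), 0)
  part2 <- optimize_partition(point, W)
  expect_identical(unclass(part), unclass(part2))
  # uniform posterior over 4 characters through a noiseless channel:
  # one character per box, 2 bits expected
  u4 <- named_posterior(rep(0.25, 4))
  part4 <- optimize_partition(u4, W)
  expect_equal(sort(as.integer(unclass(part4))), 1:4)
  expect_equal(attr(part4, "expected_information_bits"), 2)
  expect_error(optimize_partition(u4, diag(3), n_boxes = 4),
               class = "ss_invalid_argument")
})

test_that("bayes_update follows Bayes rule and ignores uninformative evidence", {
  u4 <- named_posterior(rep(0.25, 4))
  part <- structure(stats::setNames(1:4, names(u4)), n_boxes = 4L,
                    class = "ss_partition")
  flat <- query_evidence(c(1, 1, 1, 1), recognized = TRUE)
  expect_equal(as.numeric(bayes_update(u4, part, flat)), as.numeric(u4),
               tolerance = 1e-12)
  ev <- query_evidence(c(0.7, 0.1, 0.1, 0.1), recognized = TRUE)
  post <- bayes_update(u4, part, ev)
  expect_equal(as.numeric(unclass(post)), c(0.7, 0.1, 0.1, 0.1),
               tolerance = 1e-12)
  expect_equal(attr(post, "query_count"), 1L)
  # unrecognized evidence: posterior unchanged, counter incremented
  un <- query_evidence(c(1, 1, 1, 1), recognized = FALSE)
  post2 <- bayes_update(post, part, un)
  expect_equal(as.numeric(post2), as.numeric(post), tolerance = 1e-15)
  expect_equal(attr(post2, "query_count"), attr(post, "query_count"))
  expect_equal(attr(post2, "unrecognized_count"), 1L)
  expect_error(bayes_update(u4, part, query_evidence(c(0, 0, 0, 0),
                                                     recognized = TRUE)),
               class = "ss_degenerate_evidence")
})

test_that("selection threshold is strict at 0.85", {
  p86 <- named_posterior(c(0.86, rep(0.14 / 3, 3)))
  expect_equal(select_character(p86), "A")
  p84 <- named_posterior(c(0.84, rep(0.16 / 3, 3)))
  expect_true(is.na(select_character(p84)))
  p85 <- named_posterior(c(0.85, rep(0.15 / 3, 3)))
  expect_true(is.na(select_character(p85)))
})

test_that("threshold-crossing query count matches the independent recursion", {
  # engine path: repeated bayes_update along deterministic round-robin
  # partitions; oracle path: direct probability recursion (helper)
  box_lik <- c(0.85, 0.05, 0.05, 0.05)
  target <- "H"
  post <- uniform_posterior()
  n_engine <- NA_integer_
  for (q in 1:50) {
    part <- round_robin_partition(post)
    lik <- numeric(4)
    tb <- unclass(part)[[target]]
    lik[tb] <- box_lik[1]
    lik[setdiff(1:4, tb)] <- box_lik[-1]
    post <- bayes_update(post, part, query_evidence(lik, recognized = TRUE))
    if (max(post) > 0.85) { n_engine <- q; break }
  }
  n_oracle <- oracle_threshold_queries(target_idx = 8)
  expect_false(is.na(n_engine))
  expect_equal(n_engine, n_oracle)
})

test_that("run_selection types the intended character and counts time", {
  conf <- sym_channel(4, 0.9)
  user <- make_deterministic_user(c(0.95, 0.05, 0.05, 0.05) / 1.1,
                                  duration_s = 2)
  res <- run_selection("H", user, conf)
  expect_equal(res$character, "H")
  expect_equal(res$reason, "selected")
  # elapsed = 5 s display + q trials of 2 s + (q - 1) pauses of 2 s
  expect_equal(res$elapsed_s, 5 + res$n_queries * 2 + (res$n_queries - 1) * 2)
  # a 19:1 deterministic user crosses the threshold at the query count
  # predicted by the closed-form recursion with those likelihoods
  user19 <- make_deterministic_user(c(19, 1, 1, 1) / 22, duration_s = 2)
  res19 <- run_selection("H", user19, conf)
  expect_equal(res19$character, "H")
})

test_that("unrecognized input aborts after the consecutive limit", {
  conf <- sym_channel(4, 0.9)
  res <- run_selection("A", make_unrecognized_user(), conf,
                       unrecognized_limit = 10)
  expect_true(is.na(res$character))
  expect_equal(res$reason, "unrecognized-input")
  expect_equal(res$n_queries, 10L)
})

test_that("max_queries forces an argmax decision", {
  conf <- sym_channel(4, 0.9)
  # weak evidence that never crosses 85%
  weak <- make_deterministic_user(c(0.28, 0.24, 0.24, 0.24))
  res <- run_selection("A", weak, conf, max_queries = 5)
  expect_equal(res$reason, "max-queries")
  expect_true(res$forced)
  expect_equal(res$n_queries, 5L)
  expect_equal(res$character, "A")
})

test_that("posterior stays normalised and never underflows over 200 queries", {
  conf <- sym_channel(4, 0.9)
  post <- uniform_posterior()
  user <- make_deterministic_user(c(0.4, 0.2, 0.2, 0.2))
  for (q in 1:200) {
    part <- optimize_partition(post, conf)
    post <- bayes_update(post, part, user("Q", part))
    expect_equal(sum(post), 1, tolerance = 1e-12)
    expect_true(all(is.finite(unclass(post))))
  }
  expect_equal(attr(post, "query_count"), 200L)
})

simulate_selection_accuracy <- function(p, strength, n = 150) {
  conf <- sym_channel(4, p)
  user <- make_noisy_user(p, strength = strength, seed = round(p * 100))
  chars <- rep(speller_alphabet(), length.out = n)
  hits <- vapply(seq_along(chars), function(i) {
    res <- run_selection(chars[i], user, conf, max_queries = 40)
    identical(res$character, chars[i])
  }, logical(1))
  mean(hits)
}

test_that("accumulated Bayesian selection never underperforms one hard decision", {
  # evidence strength matched to the channel odds (likelihood-calibrated
  # user): stopping at posterior > 0.85 keeps accuracy above the per-query
  # channel accuracy p
  for (p in c(0.5, 0.7, 0.9)) {
    acc <- simulate_selection_accuracy(p, strength = p * 3 / (1 - p))
    expect_gte(acc, p)
  }
})

test_that("selection accuracy increases with channel accuracy", {
  # fixed decoder sharpness across channels isolates the effect of p
  accs <- vapply(c(0.5, 0.7, 0.9), simulate_selection_accuracy,
                 numeric(1), strength = 19)
  expect_true(all(diff(accs) > 0))
})
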