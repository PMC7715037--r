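# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: textbook CCA via stats::cancor, channel capacity
# by brute-force grid search, partition optimisation by exhaustive
# enumeration, and the threshold-crossing query count by direct probability
# recursion.

# First canonical correlation via stats::cancor (QR-based textbook CCA)
oracle_cca <- function(X, Y) {
  cc <- stats::cancor(X, Y)
  cc$cor[1]
}

# Mutual information (bits) of input p through row-stochastic W, from scratch
oracle_mi <- function(p, W) {
  out <- as.numeric(p %*% W)
  acc <- 0
  for (x in seq_along(p)) {
    for (y in seq_along(out)) {
      j <- p[x] * W[x, y]
      if (j > 0) acc <- acc + j * log2(j / (p[x] * out[y]))
    }
  }
  acc
}

# Channel capacity of a 3x3 matrix by grid search over the simplex
oracle_capacity_3x3 <- function(W, step = 0.01) {
  best <- 0
  for (p1 in seq(0, 1, by = step)) {
    for (p2 in seq(0, 1 - p1, by = step)) {
      p <- c(p1, p2, 1 - p1 - p2)
      best <- max(best, oracle_mi(p, W))
    }
  }
  best
}

# Exhaustive partition search: all n_boxes^n assignments of n characters
oracle_best_partition_info <- function(posterior, W, n_boxes) {
  n <- length(posterior)
  grid <- do.call(expand.grid, rep(list(seq_len(n_boxes)), n))
  best <- 0
  for (i in seq_len(nrow(grid))) {
    a <- as.integer(grid[i, ])
    p_box <- vapply(seq_len(n_boxes), function(b) sum(posterior[a == b]),
                    numeric(1))
    best <- max(best, oracle_mi(p_box, W))
  }
  best
}

# Random row-stochastic K x K matrix
random_stochastic <- function(K, seed) {
  set.seed(seed)
  m <- matrix(stats::rexp(K * K), K, K)
  m / rowSums(m)
}

# Threshold-crossing query count by direct probability recursion.  The
# posterior over 28 characters starts uniform; before each query characters
# are dealt round-robin into 4 boxes in decreasing-posterior order (ties by
# alphabet position); the box holding the target then receives likelihood
# box_lik[1] and the remaining boxes box_lik[-1] in box order.  Probabilities
# are tracked directly with cumulative products -- no package code.
oracle_threshold_queries <- function(target_idx = 8, n_chars = 28,
                                     box_lik = c(0.85, 0.05, 0.05, 0.05),
                                     threshold = 0.85, max_n = 100) {
  post <- rep(1 / n_chars, n_chars)
  for (n in seq_len(max_n)) {
    ord <- order(-post, seq_len(n_chars))
    boxes <- integer(n_chars)
    boxes[ord] <- rep_len(1:4, n_chars)
    lik <- numeric(4)
    lik[boxes[target_idx]] <- box_lik[1]
    lik[setdiff(1:4, boxes[target_idx])] <- box_lik[-1]
    post <- post * lik[boxes]
    post <- post / sum(post)
    if (max(post) > threshold) return(n)
  }
  NA_integer_
}

# Round-robin partition used to drive bayes_update along the same sequence
round_robin_partition <- function(posterior) {
  n <- length(posterior)
  ord <- order(-unclass(posterior), seq_len(n))
  boxes <- integer(n)
  boxes[ord] <- rep_len(1:4, n)
  structure(stats::setNames(boxes, names(posterior)), n_boxes = 4L,
            class = "ss_partition")
}

# Two-sided 99% binomial acceptance interval for a proportion
binom99 <- function(n, p) {
  c(stats::qbinom(0.005, n, p), stats::qbinom(0.995, n, p)) / n
}

# Hand-built session log for metric tests
make_log <- function(categories, active_s, condition = "SSBCI",
                     words = c("HOUSE")) {
  n <- length(categories)
  log <- tibble::tibble(
    timestamp_s = seq_len(n) * active_s / max(n, 1),
    event = rep("selection", n),
    character = rep("A", n),
    category = categories,
    n_queries = rep(1L, n),
    duration_s = rep(active_s / max(n, 1), n),
    reason = NA_character_,
    word = rep(words[1], n),
    typed_before = rep("", n)
  )
  log <- rbind(log, tibble::tibble(
    timestamp_s = active_s, event = "stop", character = NA_character_,
    category = NA_character_, n_queries = NA_integer_, duration_s = NA_real_,
    reason = "complete", word = NA_character_, typed_before = NA_character_
  ))
  structure(log, class = c("ss_session_log", class(log)),
            condition = condition, active_typing_time_s = active_s,
            word_list = words)
}
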