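# Separable synthetic calibration table: per-target scores tightly
# clustered so the intended target is recoverable by construction.
separable_scores <- function(n_per_target = 20, sd = 0.01, seed = 1) {
  set.seed(seed)
  centers <- matrix(0.1, 4, 4)
  diag(centers) <- 0.9
  rows <- lapply(1:4, function(tg) {
    m <- matrix(rnorm(n_per_target * 4, mean = rep(centers[tg, ],
                                                   each = n_per_target),
                      sd = sd), n_per_target, 4)
    tibble::tibble(trial_id = 0L, intended_target = tg,
                   duration_s = 6,
                   score_f1 = m[, 1], score_f2 = m[, 2],
                   score_f3 = m[, 3], score_f4 = m[, 4])
  })
  out <- dplyr::bind_rows(rows)
  out$trial_id <- seq_len(nrow(out))
  out
}

test_that("fitting requires at least five trials per target", {
  tab <- separable_scores(4)
  expect_error(fit_kde_model(tab), class = "ss_insufficient_calibration")
  expect_error(fit_kde_model(tab), "target")
})

test_that("repeated identical scores collapse to a narrow peak", {
  tab <- separable_scores(20, sd = 0.01, seed = 2)
  tab$score_f1[tab$intended_target == 1] <- 0.9
  model <- fit_kde_model(tab)
  d <- model$densities[["target_1"]][[1]]
  at_mode <- shufflespeller:::kde_eval(d, 0.9)
  away <- shufflespeller:::kde_eval(d, 0.5)
  expect_gte(at_mode / max(away, 1e-300), 10)
})

test_that("every fitted density integrates to 1 on an extended grid", {
  tab <- separable_scores(20, sd = 0.05, seed = 3)
  model <- fit_kde_model(tab)
  grid <- seq(-0.5, 1.5, length.out = 4001)
  for (dens_t in model$densities) {
    for (d in dens_t) {
      vals <- shufflespeller:::kde_eval(d, grid)
      integral <- sum((vals[-1] + vals[-length(vals)]) / 2) * diff(grid[1:2])
      expect_gte(integral, 0.99)
      expect_lte(integral, 1.01)
    }
  }
})

test_that("KDE beats a 10-bin histogram in integrated squared error", {
  set.seed(42)
  x <- stats::rbeta(2000, 2, 5)
  grid <- seq(0, 1, length.out = 801)
  truth <- stats::dbeta(grid, 2, 5)
  kde <- shufflespeller:::kde_1d(x)
  kde_vals <- shufflespeller:::kde_eval(kde, grid)
  h <- graphics::hist(x, breaks = seq(0, 1, length.out = 11), plot = FALSE)
  hist_vals <- h$density[pmin(findInterval(grid, h$breaks,
                                           rightmost.closed = TRUE), 10)]
  ise <- function(v) sum((v - truth)^2) * diff(grid[1:2])
  expect_lt(ise(kde_vals), ise(hist_vals))
})

test_that("likelihoods point to the right target and scale out in the posterior", {
  tab <- separable_scores(20, sd = 0.02, seed = 4)
  model <- fit_kde_model(tab)
  centroid3 <- colMeans(as.matrix(
    tab[tab$intended_target == 3, c("score_f1", "score_f2", "score_f3",
                                    "score_f4")]))
  lik <- class_likelihoods(model, centroid3)
  expect_equal(which.max(lik), 3)
  expect_true(all(lik > 0))
  post <- lik / sum(lik)
  post_scaled <- (7 * lik) / sum(7 * lik)
  expect_equal(post, post_scaled, tolerance = 1e-12)
  expect_error(class_likelihoods(model, c(0.5, 0.5)),
               class = "ss_invalid_argument")
})

test_that("KDE posteriors track the Gaussian discriminant closed form", {
  # two targets, one frequency, known Gaussian score distributions
  set.seed(11)
  n <- 2000
  mu <- c(0.3, 0.7); sdv <- 0.1
  tab <- tibble::tibble(
    trial_id = seq_len(2 * n),
    intended_target = rep(1:2, each = n),
    score_f1 = c(rnorm(n, mu[1], sdv), rnorm(n, mu[2], sdv))
  )
  model <- fit_kde_model(tab)
  # the expected KDE is the true density convolved with the kernel, so the
  # closed-form reference uses the kernel-widened scale
  bw <- vapply(model$densities, function(d) d[[1]]$bandwidth, numeric(1))
  probes <- seq(0.25, 0.75, length.out = 11)
  for (s in probes) {
    lik <- class_likelihoods(model, s)
    post <- lik[1] / sum(lik)
    s1 <- sqrt(sdv^2 + bw[1]^2)
    s2 <- sqrt(sdv^2 + bw[2]^2)
    closed <- stats::dnorm(s, mu[1], s1) /
      (stats::dnorm(s, mu[1], s1) + stats::dnorm(s, mu[2], s2))
    # 0.05 covers the KDE sampling error at n = 2000 (max deviation over
    # probe points measured at 0.02-0.04 across seeds of this design)
    expect_lt(abs(post - closed), 0.05)
  }
})

test_that("LOO confusion is the identity for separable calibration", {
  tab <- separable_scores(10, sd = 0.005, seed = 5)
  cm <- estimate_confusion(tab, smoothing = 0)
  expect_equal(unclass(cm), diag(4), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("confusion rows are stochastic and smoothing keeps entries positive", {
  tab <- separable_scores(20, sd = 0.3, seed = 6)
  cm <- estimate_confusion(tab, smoothing = 1)
  expect_equal(rowSums(unclass(cm)), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(unclass(cm) > 0))
  expect_gte(min(unclass(cm)), 1 / (20 + 4) * 0.999)
})

test_that("permuted labels leave no decodable information", {
  # null envelope precomputed by simulation (100 permutation draws of the
  # same design): 99% quantile of the max-row total variation from uniform
  # is 0.64; LOO decode accuracy is binomial at chance
  tab <- separable_scores(20, sd = 0.02, seed = 5)
  set.seed(5)
  tab$intended_target <- sample(tab$intended_target)
  cm <- estimate_confusion(tab, smoothing = 0.5)
  for (r in 1:4) {
    tv <- 0.5 * sum(abs(unclass(cm)[r, ] - 0.25))
    expect_lt(tv, 0.64)
  }
  acc_bounds <- binom99(80, 0.25)
  expect_gte(mean(diag(unclass(cm))), acc_bounds[1] - 0.05)
  expect_lte(mean(diag(unclass(cm))), acc_bounds[2] + 0.05)
})

test_that("LOO accuracy approaches the Bayes accuracy of the generating model", {
  # two well-separated Gaussian frequencies per target; Bayes accuracy is
  # computable from the class-conditional densities by Monte Carlo
  set.seed(21)
  n <- 120  # sessions-scale n; tolerance reflects the finite sample
  sd_gen <- 0.15
  centers <- matrix(0.2, 4, 4); diag(centers) <- 0.8
  make_tab <- function(n_per) {
    rows <- lapply(1:4, function(tg) {
      m <- matrix(rnorm(n_per * 4, rep(centers[tg, ], each = n_per), sd_gen),
                  n_per, 4)
      tibble::tibble(intended_target = tg, score_f1 = m[, 1],
                     score_f2 = m[, 2], score_f3 = m[, 3], score_f4 = m[, 4])
    })
    out <- dplyr::bind_rows(rows)
    out$trial_id <- seq_len(nrow(out))
    out
  }
  tab <- make_tab(n)
  cm <- estimate_confusion(tab, smoothing = 0)
  loo_acc <- mean(diag(unclass(cm)))
  # Bayes-optimal accuracy under the true Gaussian model, by Monte Carlo
  mc <- 4000
  correct <- 0
  for (tg in 1:4) {
    x <- matrix(rnorm(mc * 4, rep(centers[tg, ], each = mc), sd_gen), mc, 4)
    ll <- sapply(1:4, function(cl) {
      rowSums(dnorm(x, rep(centers[cl, ], each = mc), sd_gen, log = TRUE))
    })
    correct <- correct + sum(max.col(ll) == tg)
  }
  bayes_acc <- correct / (4 * mc)
  expect_lt(abs(loo_acc - bayes_acc), 0.05)
})

test_that("gaze model: confusion tends to identity as scatter shrinks", {
  calib <- generate_gaze_calibration(n_per_target = 8, duration_s = 1,
                                     scatter_deg = 0.01, dropout_rate = 0,
                                     seed = 9)
  feats <- gaze_feature_table(calib)
  cm <- estimate_confusion(feats, smoothing = 0)
  expect_equal(unclass(cm), diag(4), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("low-validity gaze trials are unrecognized, not forced", {
  calib <- generate_gaze_calibration(n_per_target = 6, duration_s = 1,
                                     scatter_deg = 0.5, dropout_rate = 0.9,
                                     seed = 10)
  feats <- gaze_feature_table(calib)
  expect_true(any(!feats$recognized))
  model_lik <- class_likelihoods(
    fit_gaze_model(gaze_feature_table(
      generate_gaze_calibration(n_per_target = 6, duration_s = 1,
                                scatter_deg = 0.5, dropout_rate = 0,
                                seed = 11))),
    c(NA_real_, NA_real_))
  expect_true(all(model_lik == 0))
})

test_that("fitted models reload from JSON with identical likelihoods", {
  tab <- separable_scores(8, sd = 0.05, seed = 12)
  model <- fit_kde_model(tab)
  path <- file.path(tempdir(), "model.json")
  write_kde_model(model, path)
  back <- read_kde_model(path)
  probe <- c(0.4, 0.2, 0.6, 0.8)
  expect_equal(class_likelihoods(back, probe),
               class_likelihoods(model, probe), tolerance = 1e-12)
})
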