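test_that("QUEST posterior is a valid pmf after init and arbitrary updates", {
  set.seed(2)
  st <- quest_init()
  expect_equal(sum(st$posterior), 1, tolerance = 1e-12)
  expect_true(all(st$posterior >= 0))
  # with a prior well inside the grid the posterior mean is the prior mean
  st_in <- quest_init(quest_config(prior_mean = 1.3, prior_sd = 0.2))
  expect_equal(quest_estimate(st_in)[["mean"]], 1.3, tolerance = 0.01)
  for (i in 1:40) {
    st <- quest_update(st, 10^runif(1, 0.5, 2.1), runif(1) < 0.7)
    expect_equal(sum(st$posterior), 1, tolerance = 1e-12)
    expect_true(all(st$posterior >= 0))
  }
})

test_that("a near-flat prior yields a near-uniform posterior", {
  st <- quest_init(quest_config(prior_sd = 1e4))
  expect_lt(max(st$posterior) / min(st$posterior), 1.01)
})

test_that("QUEST update equals the brute-force grid Bayes oracle", {
  cfg <- quest_config()
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    levels <- 10^runif(n, 0.5, 2.2)
    correct <- runif(n) < 0.7
    st <- quest_init(cfg)
    for (i in seq_len(n)) st <- quest_update(st, levels[i], correct[i])
    orc <- oracle_posterior(cfg, levels, correct)
    expect_lt(max(abs(st$posterior - orc)), 1e-10)
    m_orc <- sum(st$grid * orc)
    expect_equal(quest_estimate(st)[["mean"]], m_orc, tolerance = 1e-10)
  }
})

test_that("QUEST updates commute over trial order", {
  cfg <- quest_config()
  levels <- c(40, 90, 60, 120, 30)
  correct <- c(TRUE, FALSE, TRUE, FALSE, TRUE)
  st1 <- quest_init(cfg)
  for (i in 1:5) st1 <- quest_update(st1, levels[i], correct[i])
  perm <- c(3, 5, 1, 4, 2)
  st2 <- quest_init(cfg)
  for (i in perm) st2 <- quest_update(st2, levels[i], correct[i])
  expect_equal(st1$posterior, st2$posterior, tolerance = 1e-12)
})

test_that("a correct response at an easy (coarse) level never lowers the mean", {
  # monotone likelihood ratio: seeing an easy stimulus is evidence for a
  # higher (finer) threshold
  st <- quest_init()
  m0 <- quest_estimate(st)[["mean"]]
  st2 <- quest_update(st, level_ppd = 5, correct = TRUE)
  expect_gte(quest_estimate(st2)[["mean"]], m0 - 1e-12)
  # and an error at a coarse level drags the mean down
  st3 <- quest_update(st, level_ppd = 5, correct = FALSE)
  expect_lt(quest_estimate(st3)[["mean"]], m0)
})

test_that("quest_estimate matches brute-force moments on degenerate posteriors", {
  st <- quest_init()
  # symmetric posterior about the grid centre
  centre <- (st$config$grid_min + st$config$grid_max) / 2
  st$posterior <- dnorm(st$grid, centre, 0.2)
  st$posterior <- st$posterior / sum(st$posterior)
  expect_equal(quest_estimate(st)[["mean"]], centre, tolerance = 1e-10)
  # point mass has sd 0
  st$posterior <- rep(0, length(st$grid))
  st$posterior[101] <- 1
  est <- quest_estimate(st)
  expect_equal(est[["mean"]], st$grid[101])
  expect_equal(est[["sd"]], 0)
})

test_that("degenerate grids and underflow are reported as errors", {
  expect_error(quest_init(quest_config(grid_min = 2, grid_max = 1)),
               "degenerate")
  expect_error(quest_init(quest_config(delta = 0.2)), "delta")
})

test_that("2IFC sessions respect the trial-count and stopping contract", {
  obs <- sample_population(2, seed = 40)[[1]]
  tr <- run_2ifc_session(obs, eccentricity_deg = 0, seed = 9)
  counts <- table(tr$channel)
  expect_true(all(counts >= 30 & counts <= 50))
  expect_true(all(tr$repeat_index %in% 1:3))
  ests <- attr(tr, "estimates")
  # every stopped track either hit the SD criterion or the trial cap
  expect_true(all(ests$sd_log10 <= 0.07 | ests$n_trials >= 50))
  # same seed reproduces the identical trial list
  tr2 <- run_2ifc_session(obs, eccentricity_deg = 0, seed = 9)
  expect_identical(tr, tr2)
  # different seed gives a different list
  tr3 <- run_2ifc_session(obs, eccentricity_deg = 0, seed = 10)
  expect_false(identical(tr$correct, tr3$correct))
  # interleaving preserves within-track ordering
  for (ch in unique(tr$channel)) {
    expect_identical(tr$trial_index[tr$channel == ch],
                     seq_len(sum(tr$channel == ch)))
  }
  expect_error(run_2ifc_session(obs, channels = "XX", eccentricity_deg = 0),
               "no threshold")
})

test_that("sessions recover a sharp observer's threshold reliably", {
  # near-infallible observer: steep slope, tiny lapse
  pop <- default_population()
  hits <- 0
  n_rep <- 60
  for (s in seq_len(n_rep)) {
    obs <- simulated_observer(
      "sharp", data.frame(channel = "Ach", eccentricity_deg = 0,
                          threshold_ppd = 80),
      slope = 12, lapse = 0)
    tr <- run_2ifc_session(obs, channels = "Ach", eccentricity_deg = 0,
                           seed = 1000 + s)
    est <- attr(tr, "estimates")$mean_log10_ppd
    if (abs(est - log10(80)) < 0.1) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("MLE recovers a known Weibull from simulated trials within 5%", {
  set.seed(5)
  lev <- 10^seq(log10(20), log10(80), length.out = 10)
  lv <- rep(lev, each = 50)
  p <- oracle_p_correct(lv, tau_ppd = 40, beta = 3.5, delta = 0.02)
  trials <- data.frame(level_ppd = lv,
                       correct = as.integer(runif(length(lv)) < p))
  fit <- fit_psychometric_mle(trials)
  expect_equal(fit$threshold_ppd, 40, tolerance = 0.05)
  expect_false(fit$boundary_flag)
  expect_lte(fit$loglik, 0)
  # fitted curve respects the 2IFC floor everywhere
  pr <- psychometric_2ifc(seq(0.3, 2.3, 0.1), log10(fit$threshold_ppd),
                          beta = fit$slope, delta = fit$lapse)
  expect_true(all(pr >= 0.5 - 1e-12))
})

test_that("MLE threshold is robust to chance-level trials far above threshold", {
  set.seed(6)
  lev <- 10^seq(log10(20), log10(80), length.out = 10)
  lv <- rep(lev, each = 30)
  p <- oracle_p_correct(lv, 40, 3.5, 0.02)
  trials <- data.frame(level_ppd = lv,
                       correct = as.integer(runif(length(lv)) < p))
  far <- data.frame(level_ppd = rep(190, 10),
                    correct = as.integer(runif(10) < 0.5))
  f1 <- fit_psychometric_mle(trials)
  f2 <- fit_psychometric_mle(rbind(trials, far))
  expect_equal(f2$threshold_ppd / f1$threshold_ppd, 1, tolerance = 0.02)
})

test_that("MLE flags degenerate all-identical response sets without error", {
  trials <- data.frame(level_ppd = rep(c(30, 40, 50, 60), each = 3),
                       correct = 1L)
  fit <- fit_psychometric_mle(trials)
  expect_true(fit$boundary_flag)
  expect_equal(log10(fit$threshold_ppd), 2.3, tolerance = 1e-3)
  expect_error(fit_psychometric_mle(trials[1:6, ]), "10 trials")
  one_level <- data.frame(level_ppd = rep(40, 12), correct = rep(0:1, 6))
  expect_error(fit_psychometric_mle(one_level), "distinct levels")
})

test_that("modified Z-score flags the hand-computed outlier", {
  v <- c(1:9, 100)
  flags <- detect_outliers_modz(v)
  # oracle: median 5.5, MAD 2.5 -> Z(100) = 0.6745 * 94.5 / 2.5 = 25.5
  expect_equal(attr(flags, "z")[10], 0.6745 * 94.5 / 2.5, tolerance = 1e-12)
  expect_identical(which(as.logical(flags)), 10L)
  expect_false(any(detect_outliers_modz(rep(7, 5))))
})

test_that("modified Z-score is affine invariant and has a zero-MAD fallback", {
  set.seed(8)
  v <- c(rnorm(20), 25)
  f1 <- as.logical(detect_outliers_modz(v))
  f2 <- as.logical(detect_outliers_modz(3.7 * v - 12))
  expect_identical(f1, f2)
  # MAD = 0 but data not constant: falls back to mean absolute deviation
  v0 <- c(rep(5, 8), 50)
  f3 <- detect_outliers_modz(v0)
  expect_true(as.logical(f3)[9])
  expect_false(any(as.logical(f3)[1:8]))
})
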