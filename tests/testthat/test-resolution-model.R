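test_that("sensitivity and threshold_frequency are a consistent inverse pair", {
  set.seed(11)
  for (i in 1:50) {
    p <- channel_params(sample(c("Ach", "RG", "YV"), 1),
                        A = runif(1, 5, 80), k_e = runif(1, 0.01, 0.6),
                        contrast = runif(1, 0.1, 1), S0 = runif(1, 50, 5000))
    e <- runif(1, 0, 30)
    rho <- threshold_frequency(p, e)
    expect_equal(sensitivity(p, e, rho), 1 / p$contrast, tolerance = 1e-12)
  }
})

test_that("sensitivity is monotone decreasing in frequency and eccentricity", {
  p <- channel_params("Ach", A = 47, k_e = 0.13)
  rho <- seq(1, 40, by = 1)
  s <- sensitivity(p, 0, rho)
  expect_true(all(diff(s) < 0))
  expect_true(all(sensitivity(p, 10, rho) < sensitivity(p, 0, rho)))
  # rho -> 0 limit approaches the baseline S0
  expect_equal(sensitivity(p, 0, 1e-9), p$S0, tolerance = 1e-6)
})

test_that("threshold frequency follows A / (1 + k_e e) and its printed algebra", {
  p <- channel_params("Ach", A = 47, k_e = 0.13)
  expect_equal(threshold_frequency(p, 0), 47)
  expect_equal(threshold_frequency(p, 0, units = "ppd"), 94)
  # 2.3x decline at 10 deg implies k_e = 0.13 and a 3.6x decline at 20 deg
  expect_equal(threshold_frequency(p, 0) / threshold_frequency(p, 10), 2.3)
  expect_equal(threshold_frequency(p, 0) / threshold_frequency(p, 20), 3.6)
  e <- seq(0, 30, by = 0.5)
  rho <- threshold_frequency(p, e)
  expect_true(all(diff(rho) < 0))          # strictly decreasing
  expect_true(all(diff(diff(rho)) > 0))    # convex
})

test_that("threshold predictions are invariant to the log base and to S0", {
  # base-10 vs natural log parameterisations of the same sensitivity curve
  # give identical thresholds because the base cancels in the ratio
  for (S0 in c(100, 500, 5000)) {
    p <- channel_params("Ach", A = 47, k_e = 0.13, S0 = S0)
    S <- 1 / p$contrast
    k_rho_ln <- log(S / S0) / 47           # natural-log slope
    rho_ln <- (log(S) - log(S0)) / (k_rho_ln * (1 + 0.13 * 10))
    expect_equal(threshold_frequency(p, 10), rho_ln, tolerance = 1e-12)
  }
})

test_that("fit recovers exact parameters from noiseless data", {
  e <- c(0, 10, 20)
  truth <- channel_params("Ach", A = 47, k_e = 0.13)
  rec <- threshold_records(
    observer_id = rep(c("a", "b"), each = 3), channel = "Ach",
    eccentricity_deg = rep(e, 2),
    threshold_ppd = rep(threshold_frequency(truth, e, units = "ppd"), 2))
  fit <- fit_channel_params(rec)
  expect_equal(fit$A, 47, tolerance = 1e-9)
  expect_equal(fit$k_e, 0.13, tolerance = 1e-9)
  expect_lt(attr(fit, "rmse_cpd"), 1e-9)
})

test_that("two-point median fit matches the closed-form oracle", {
  orc <- oracle_two_point_fit(47, 47 / 2.3, 10)
  rec <- threshold_records(c("m", "m"), "Ach", c(0, 10),
                           2 * c(47, 47 / 2.3))
  fit <- fit_channel_params(rec)
  expect_equal(fit$A, orc$A, tolerance = 1e-8)
  expect_equal(fit$k_e, orc$k_e, tolerance = 1e-8)
  expect_equal(fit$k_e, 0.13, tolerance = 1e-8)
})

test_that("fit is scale-equivariant: doubling thresholds doubles A only", {
  set.seed(4)
  e <- rep(c(0, 10, 20), each = 6)
  base <- 2 * 47 / (1 + 0.13 * e) * exp(rnorm(length(e), 0, 0.05))
  r1 <- threshold_records(seq_along(e), "Ach", e, base)
  r2 <- threshold_records(seq_along(e), "Ach", e, 2 * base)
  f1 <- fit_channel_params(r1)
  f2 <- fit_channel_params(r2)
  expect_equal(f2$A / f1$A, 2, tolerance = 1e-6)
  expect_equal(f2$k_e, f1$k_e, tolerance = 1e-6)
})

test_that("fit recovers parameters within 5% RMSE under 10% lognormal noise", {
  set.seed(21)
  e <- rep(c(0, 10, 20), each = 18)
  errs <- replicate(100, {
    ppd <- 2 * 47 / (1 + 0.13 * e) * exp(rnorm(length(e), 0, 0.1))
    f <- fit_channel_params(threshold_records(seq_along(e), "Ach", e, ppd))
    c(f$A / 47 - 1, f$k_e / 0.13 - 1)
  })
  expect_lt(sqrt(mean(errs[1, ]^2)), 0.05)
  expect_lt(sqrt(mean(errs[2, ]^2)), 0.05)
})

test_that("fit refuses underdetermined designs", {
  rec <- threshold_records(c("a", "b"), "Ach", c(10, 10), c(40, 44))
  expect_error(fit_channel_params(rec), "distinct eccentricities")
})

test_that("fit_population computes per-knot mean and n-1 SD", {
  rec <- threshold_records(c("a", "b"), "Ach", c(0, 0), c(90, 98))
  pop <- fit_population(rec)
  expect_equal(pop$mu_ppd, 94)
  expect_equal(pop$sigma_ppd, sqrt(32))
  # identical observers give sigma 0
  rec2 <- threshold_records(c("a", "b", "c"), "RG", c(0, 0, 0), c(50, 50, 50))
  expect_equal(fit_population(rec2)$sigma_ppd, 0)
  # a knot with one observer errors, naming the knot
  rec3 <- rbind(rec, threshold_records("a", "Ach", 10, 40))
  expect_error(fit_population(rec3), "10")
})

test_that("fit_population recovers a generating Gaussian at n = 1000", {
  set.seed(33)
  draws <- rnorm(1000, 94, 10)
  rec <- threshold_records(seq_along(draws), "Ach", 0, abs(draws))
  pop <- fit_population(rec)
  expect_lt(abs(pop$mu_ppd - 94), 3 * 10 / sqrt(1000))
})

test_that("population percentiles interpolate and order correctly", {
  pop <- default_population()
  # p = 50 at a knot returns the knot mean exactly
  expect_equal(as.numeric(population_percentile(pop, "Ach", 0, 50)), 94)
  expect_equal(as.numeric(population_percentile(pop, "Ach", 20, 50)), 22)
  # Gaussian symmetry about the median
  up <- as.numeric(population_percentile(pop, "Ach", 20, 95))
  lo <- as.numeric(population_percentile(pop, "Ach", 20, 5))
  expect_equal(up - 22, 22 - lo, tolerance = 1e-9)
  # quantile ordering preserved at on- and off-knot eccentricities
  for (e in c(0, 5, 10, 15, 20, 25)) {
    q <- sapply(c(5, 25, 50, 75, 95),
                function(p) as.numeric(population_percentile(pop, "Ach", e, p)))
    expect_true(all(diff(q) > 0) || all(q == 0))
  }
  # midpoint interpolation of mu
  expect_equal(as.numeric(population_percentile(pop, "Ach", 5, 50)),
               (94 + 94 / 2.3) / 2, tolerance = 1e-9)
  # extrapolation beyond the last knot is flagged and floored at zero
  far <- population_percentile(pop, "YV", 80, 5)
  expect_true(attr(far, "extrapolated"))
  expect_gte(as.numeric(far), 0)
})

test_that("ideal display curve inverts the geometry at the chosen percentile", {
  pop <- default_population()
  cur <- ideal_display_curve(pop, "Ach", p = 95,
                             distance_heights = c(1, 2, 4, 6, 8))
  expect_true(all(diff(cur$lines) < 0))  # fewer lines needed further away
  # consistency: the reported line count reaches the target ppd exactly
  for (i in seq_len(nrow(cur))) {
    expect_equal(display_ppd(cur$lines[i], cur$distance_heights[i]),
                 cur$target_ppd[1], tolerance = 1e-6)
  }
  # halving the threshold halves the required lines (small-angle)
  cur50 <- ideal_display_curve(
    population_model(data.frame(channel = "Ach", eccentricity_deg = 0,
                                mu_ppd = cur$target_ppd[1] / 2,
                                sigma_ppd = 0)),
    "Ach", p = 50, distance_heights = 4)
  expect_equal(cur50$lines / cur$lines[cur$distance_heights == 4], 0.5,
               tolerance = 1e-3)
  ppi <- ideal_display_curve(pop, "Ach", p = 50, distance_m = c(0.5, 1, 2))
  expect_true(all(diff(ppi$ppi) < 0))
})

test_that("threshold tables validate channels and positivity", {
  expect_error(threshold_records("a", "XY", 0, 60), "unknown channel")
  expect_error(threshold_records("a", "Ach", 0, -1), "positive")
  expect_error(threshold_records("a", "Ach", -5, 60), ">= 0")
})
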