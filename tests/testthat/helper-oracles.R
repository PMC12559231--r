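# Independent oracles used across the suite.

# Brute-force grid Bayes for a sequence of 2IFC trials: recompute the
# posterior directly from the prior and the likelihood product, without the
# package's sequential update path.
oracle_posterior <- function(cfg, levels_ppd, correct) {
  grid <- seq(cfg$grid_min, cfg$grid_max, by = cfg$grid_step)
  post <- dnorm(grid, cfg$prior_mean, cfg$prior_sd)
  for (i in seq_along(levels_ppd)) {
    p <- 1 - cfg$delta - (1 - cfg$delta - cfg$gamma) *
      exp(log(1 - cfg$q) * 10^(cfg$beta * (grid - log10(levels_ppd[i]))))
    post <- post * if (correct[i]) p else 1 - p
  }
  post / sum(post)
}

# Closed-form (A, k_e) from two aggregate threshold frequencies.
oracle_two_point_fit <- function(rho0, rho_e, e) {
  list(A = rho0, k_e = (rho0 / rho_e - 1) / e)
}

# Exact fundamental amplitude of a unit square wave sampled at period_px
# samples per period: 4 / (P * sin(pi / P)) -> 4/pi as P grows.
oracle_sampled_square_fundamental <- function(period_px) {
  4 / (period_px * sin(pi / period_px))
}

# Reference psychometric probability (duplicated independently of the
# package implementation).
oracle_p_correct <- function(level_ppd, tau_ppd, beta, delta, q = 0.5) {
  1 - delta - (1 - delta - 0.5) *
    exp(log(1 - q) * 10^(beta * (log10(tau_ppd) - log10(level_ppd))))
}

rand_sRGB <- function(n, lo = 0.35, hi = 0.65) {
  array(runif(n * n * 3, lo, hi), c(n, n, 3))
}
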