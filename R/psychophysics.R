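# QUEST adaptive staircase, 2IFC session logic, psychometric MLE and
# modified Z-score outlier rejection.
#
# Stimulus "level" is the tested resolution in pixels per degree. Unlike the
# usual intensity convention, a HIGHER level is a HARDER stimulus (finer
# pixels), so the psychometric function is decreasing in level: performance
# is at the 1 - lapse ceiling for coarse stimuli and falls to the 0.5
# guessing floor above the observer's resolution limit.
#
# The 2IFC Weibull family used throughout (QUEST likelihood, response
# simulation, MLE) is, with x = log10(level), t = log10(threshold):
#
#   p(correct | x) = 1 - delta - (1 - delta - gamma) *
#                      exp(log(1 - q) * 10^(beta * (t - x)))
#
# where gamma = 0.5 (2IFC guess rate), delta is the lapse rate and
# q is the threshold criterion expressed as a fraction of the way from gamma
# to 1 - delta (default 0.5). The log(1 - q) factor places the location
# parameter t exactly at the criterion performance level, so the threshold
# reported by every component refers to the same point on the curve.

#' 2IFC psychometric function (decreasing in stimulus level)
#'
#' @param level_log10 log10 of the tested level in ppd.
#' @param threshold_log10 log10 of the threshold level in ppd (the level at
#'   which performance is the criterion fraction `q` of the way from the
#'   guess rate to the lapse ceiling).
#' @param beta Weibull slope (> 0).
#' @param gamma Guess rate (0.5 for 2IFC).
#' @param delta Lapse rate in [0, 0.1).
#' @param q Threshold criterion fraction in (0, 1); default midway.
#' @return Probability of a correct response.
#' @export
psychometric_2ifc <- function(level_log10, threshold_log10, beta = 3.5,
                              gamma = 0.5, delta = 0.02, q = 0.5) {
  stopifnot(beta > 0, gamma >= 0, gamma < 1, delta >= 0, delta < 0.1,
            q > 0, q < 1)
  1 - delta - (1 - delta - gamma) *
    exp(log(1 - q) * 10^(beta * (threshold_log10 - level_log10)))
}

#' Default QUEST configuration
#'
#' Grid over log10 threshold ppd on [0.3, 2.3] (2 to 200 ppd) at 0.01 steps,
#' a Gaussian prior, Weibull slope 3.5, 2IFC guess rate 0.5 and a small
#' assumed lapse rate.
#'
#' @param grid_min,grid_max,grid_step Grid over log10(threshold ppd).
#' @param prior_mean,prior_sd Gaussian prior in log10 ppd.
#' @param beta,gamma,delta,q Psychometric family settings (see
#'   [psychometric_2ifc()]).
#' @param placement How the next test level is chosen from the posterior:
#'   `"mean"` (default), `"mode"` or `"median"`.
#' @return A named list.
#' @export
quest_config <- function(grid_min = 0.3, grid_max = 2.3, grid_step = 0.01,
                         prior_mean = log10(60), prior_sd = 0.6,
                         beta = 3.5, gamma = 0.5, delta = 0.02, q = 0.5,
                         placement = c("mean", "mode", "median")) {
  placement <- match.arg(placement)
  list(grid_min = grid_min, grid_max = grid_max, grid_step = grid_step,
       prior_mean = prior_mean, prior_sd = prior_sd,
       beta = beta, gamma = gamma, delta = delta, q = q,
       placement = placement)
}

#' Initialise a QUEST staircase
#'
#' The posterior over log10(threshold ppd) starts as a Gaussian prior
#' evaluated on the discrete grid and renormalised.
#'
#' @param config A [quest_config()] list.
#' @return An object of class `quest_state`.
#' @export
quest_init <- function(config = quest_config()) {
  if (!(config$grid_step > 0) || !(config$grid_min < config$grid_max)) {
    stop("degenerate QUEST grid: need grid_min < grid_max and grid_step > 0")
  }
  if (config$delta < 0 || config$delta >= 0.1) {
    stop("delta must be in [0, 0.1)")
  }
  grid <- seq(config$grid_min, config$grid_max, by = config$grid_step)
  if (length(grid) < 3) stop("degenerate QUEST grid: fewer than 3 points")
  post <- stats::dnorm(grid, config$prior_mean, config$prior_sd)
  s <- sum(post)
  if (s <= 0) stop("prior has zero mass on the grid")
  structure(
    list(grid = grid, posterior = post / s, config = config, n_trials = 0L),
    class = "quest_state"
  )
}

#' Bayesian update of a QUEST staircase after one response
#'
#' Multiplies the posterior by the 2IFC Weibull likelihood of the observed
#' response at the tested level and renormalises. Updates commute over trial
#' order.
#'
#' @param state A `quest_state`.
#' @param level_ppd Tested level in ppd (> 0).
#' @param correct Logical or 0/1 response.
#' @return The updated `quest_state`.
#' @export
quest_update <- function(state, level_ppd, correct) {
  stopifnot(inherits(state, "quest_state"), level_ppd > 0)
  correct <- as.logical(correct)
  stopifnot(length(correct) == 1, !is.na(correct))
  cfg <- state$config
  p <- psychometric_2ifc(log10(level_ppd), state$grid, beta = cfg$beta,
                         gamma = cfg$gamma, delta = cfg$delta, q = cfg$q)
  lik <- if (correct) p else 1 - p
  post <- state$posterior * lik
  s <- sum(post)
  if (s <= 0 || !is.finite(s)) {
    stop("QUEST posterior underflowed to zero mass")
  }
  state$posterior <- post / s
  state$n_trials <- state$n_trials + 1L
  state
}

#' Posterior mean and SD of a QUEST staircase
#'
#' @param state A `quest_state`.
#' @return Named numeric vector `c(mean, sd)` in log10 ppd units.
#' @export
quest_estimate <- function(state) {
  stopifnot(inherits(state, "quest_state"))
  m <- sum(state$grid * state$posterior)
  v <- sum((state$grid - m)^2 * state$posterior)
  c(mean = m, sd = sqrt(max(v, 0)))
}

quest_next_level <- function(state) {
  cfg <- state$config
  x <- switch(cfg$placement,
    mean = quest_estimate(state)[["mean"]],
    mode = state$grid[which.max(state$posterior)],
    median = {
      cum <- cumsum(state$posterior)
      state$grid[which(cum >= 0.5)[1]]
    })
  10^x
}

#' Simulate an interleaved 2IFC QUEST session for one observer
#'
#' Maintains one QUEST staircase per requested channel at a fixed
#' eccentricity. On every step one still-active track is drawn at random
#' (seeded), its next level is taken from the posterior, and the stimulus is
#' presented `n_repeats` times consecutively with independent simulated
#' responses, each fed back into the staircase. A track stops once its
#' posterior SD falls to `stop_sd` (log10 units) after at least `min_trials`
#' responses, or at `max_trials` responses (the final repeat block is
#' truncated so the cap is never exceeded).
#'
#' @param observer A [simulated_observer()].
#' @param channels Channels to interleave (default all three).
#' @param eccentricity_deg Eccentricity of the session in degrees.
#' @param seed Integer seed; the full trial list is a deterministic function
#'   of (observer, arguments, seed).
#' @param config QUEST configuration ([quest_config()]).
#' @param min_trials,max_trials Per-track response-count bounds.
#' @param stop_sd Posterior-SD stopping criterion in log10 units.
#' @param n_repeats Consecutive presentations per selected level.
#' @param aggregate_repeats If `TRUE`, the repeats of a block are scored as a
#'   single majority-vote response for the staircase update (the individual
#'   responses are still recorded); default scores each repeat individually.
#' @return data.frame of trial records with columns `track_id, channel,
#'   eccentricity_deg, trial_index, repeat_index, level_ppd, correct`, plus
#'   attribute `estimates`: per-channel posterior mean/SD (log10 ppd).
#' @export
run_2ifc_session <- function(observer, channels = c("Ach", "RG", "YV"),
                             eccentricity_deg = 0, seed = 1,
                             config = quest_config(),
                             min_trials = 30, max_trials = 50,
                             stop_sd = 0.07, n_repeats = 3,
                             aggregate_repeats = FALSE) {
  stopifnot(inherits(observer, "simulated_observer"),
            min_trials >= 1, max_trials >= min_trials, n_repeats >= 1)
  for (ch in channels) {
    observer_threshold(observer, ch, eccentricity_deg)  # errors if missing
  }
  states <- stats::setNames(
    lapply(channels, function(ch) quest_init(config)), channels)
  active <- stats::setNames(rep(TRUE, length(channels)), channels)
  rows <- vector("list", 0)
  trial_counter <- stats::setNames(rep(0L, length(channels)), channels)

  rng <- local_rng(derive_seed(seed, "session", observer$id, eccentricity_deg))
  on.exit(rng$restore(), add = TRUE)

  while (any(active)) {
    live <- names(active)[active]
    ch <- if (length(live) == 1) live else sample(live, 1)
    st <- states[[ch]]
    level <- quest_next_level(st)
    k <- min(n_repeats, max_trials - trial_counter[[ch]])
    resp <- logical(k)
    for (r in seq_len(k)) {
      resp[r] <- simulate_response(observer, ch, eccentricity_deg, level)
      trial_counter[[ch]] <- trial_counter[[ch]] + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        track_id = paste0(ch, "_e", eccentricity_deg),
        channel = ch, eccentricity_deg = eccentricity_deg,
        trial_index = trial_counter[[ch]], repeat_index = r,
        level_ppd = level, correct = as.integer(resp[r]),
        stringsAsFactors = FALSE)
    }
    if (aggregate_repeats) {
      st <- quest_update(st, level, mean(resp) >= 0.5)
    } else {
      for (r in seq_len(k)) st <- quest_update(st, level, resp[r])
    }
    states[[ch]] <- st
    est <- quest_estimate(st)
    n <- trial_counter[[ch]]
    if (n >= max_trials || (n >= min_trials && est[["sd"]] <= stop_sd)) {
      active[[ch]] <- FALSE
    }
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ests <- t(vapply(channels, function(ch) quest_estimate(states[[ch]]),
                   numeric(2)))
  attr(out, "estimates") <- data.frame(
    channel = channels, eccentricity_deg = eccentricity_deg,
    mean_log10_ppd = ests[, 1], sd_log10 = ests[, 2],
    n_trials = as.integer(trial_counter[channels]),
    stringsAsFactors = FALSE)
  out
}

#' Maximum-likelihood psychometric fit to 2IFC trial data
#'
#' Maximises the Bernoulli log-likelihood of the decreasing 2IFC Weibull
#' ([psychometric_2ifc()]) in log10 ppd with the guess rate fixed at 0.5,
#' the slope in `[0.5, 20]` and the lapse rate in `[0, 0.05]`. The reported
#' threshold is the level at which performance is the criterion fraction `q`
#' of the way between the guess rate and the lapse ceiling.
#'
#' @param trials data.frame with columns `level_ppd` and `correct` (0/1), as
#'   produced by [run_2ifc_session()].
#' @param q Threshold criterion fraction (default midway).
#' @param t_bounds Box bounds on log10 threshold ppd.
#' @param beta_bounds Box bounds on the slope.
#' @param lapse_max Upper bound on the lapse rate.
#' @return An object of class `psychometric_fit`: list with
#'   `threshold_ppd, slope, lapse, loglik, converged, boundary_flag`.
#' @export
fit_psychometric_mle <- function(trials, q = 0.5,
                                 t_bounds = c(0.3, 2.3),
                                 beta_bounds = c(0.5, 20),
                                 lapse_max = 0.05) {
  stopifnot(all(c("level_ppd", "correct") %in% names(trials)))
  lv <- log10(trials$level_ppd)
  y <- as.integer(trials$correct)
  if (nrow(trials) < 10) stop("need at least 10 trials")
  if (length(unique(round(lv, 10))) < 3) {
    stop("need trials spanning at least 3 distinct levels")
  }

  nll <- function(par) {
    p <- psychometric_2ifc(lv, par[1], beta = par[2], gamma = 0.5,
                           delta = par[3], q = q)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }

  lower <- c(t_bounds[1], beta_bounds[1], 0)
  upper <- c(t_bounds[2], beta_bounds[2], lapse_max)
  degenerate <- length(unique(y)) == 1
  starts <- list(c(stats::median(lv), 3.5, 0.01),
                 c(stats::quantile(lv, 0.25)[[1]], 2, 0.01),
                 c(stats::quantile(lv, 0.75)[[1]], 6, 0.02))
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower + 1e-6), upper - 1e-6)
    fit <- tryCatch(
      stats::optim(s, nll, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("psychometric MLE failed from all starts")

  par <- best$par
  tol <- 1e-6
  at_bound <- (par[1] <= lower[1] + tol) || (par[1] >= upper[1] - tol) ||
    (par[2] <= lower[2] + tol) || (par[2] >= upper[2] - tol) ||
    (par[3] >= upper[3] - tol)
  structure(
    list(threshold_ppd = 10^par[1], slope = par[2], lapse = par[3],
         loglik = -best$value,
         converged = best$convergence == 0 && !degenerate,
         boundary_flag = at_bound || degenerate),
    class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit> threshold = %.3g ppd, slope = %.3g, lapse = %.3g, loglik = %.2f%s\n",
    x$threshold_ppd, x$slope, x$lapse, x$loglik,
    if (x$boundary_flag) " [boundary]" else ""))
  invisible(x)
}

#' Modified Z-score outlier detection
#'
#' Flags values whose modified Z-score `0.6745 * (x - median) / MAD` exceeds
#' `cutoff` in absolute value, where MAD is the raw median absolute
#' deviation from the median. When the MAD is zero but the data are not
#' constant, the score falls back to the mean absolute deviation
#' (`(x - median) / (1.253314 * meanAD)`, the Iglewicz-Hoaglin variant);
#' constant data yield no outliers.
#'
#' @param values Numeric vector (length >= 3).
#' @param cutoff Threshold on |Z| (default 3.5).
#' @return Logical vector of flags, with attribute `z` (the scores).
#' @examples
#' detect_outliers_modz(c(1:9, 100))  # flags the 100
#' @export
detect_outliers_modz <- function(values, cutoff = 3.5) {
  stopifnot(is.numeric(values), length(values) >= 3, all(is.finite(values)),
            cutoff > 0)
  med <- stats::median(values)
  dev <- values - med
  mad_raw <- stats::median(abs(dev))
  if (mad_raw > 0) {
    z <- 0.6745 * dev / mad_raw
  } else {
    mean_ad <- mean(abs(dev))
    if (mean_ad == 0) {
      z <- rep(0, length(values))  # constant data
    } else {
      z <- dev / (1.253314 * mean_ad)
    }
  }
  flags <- abs(z) > cutoff
  attr(flags, "z") <- z
  flags
}
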