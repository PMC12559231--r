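# Synthetic observers, simulated 2IFC responses and stimulus images.
#
# The generator emulates the study design: per-observer true thresholds are
# drawn from the eccentricity-interpolated Gaussian population model per
# colour channel (truncated positive, monotone non-increasing with
# eccentricity), and binary 2IFC responses follow the decreasing Weibull
# psychometric family shared with the QUEST engine.

# Deterministic 31-bit seed derived from a master seed and labels, so that
# nested components can draw from reproducible named substreams.
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "|")
  h <- 0
  for (code in utf8ToInt(parts)) h <- (h * 131 + code) %% 2147483629
  as.integer((h + as.integer(seed) %% 2147483629) %% 2147483629)
}

# Scoped RNG: seeds the global stream and restores the previous state on
# restore(), so library functions do not disturb the caller's RNG.
local_rng <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  list(restore = function() {
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
}

#' Construct a simulated observer
#'
#' @param id Observer label.
#' @param thresholds data.frame with columns `channel, eccentricity_deg,
#'   threshold_ppd` giving the observer's true resolution limits.
#' @param slope Weibull psychometric slope.
#' @param lapse Lapse rate in [0, 0.05].
#' @return An object of class `simulated_observer`.
#' @export
simulated_observer <- function(id, thresholds, slope = 3.5, lapse = 0.02) {
  stopifnot(all(c("channel", "eccentricity_deg", "threshold_ppd") %in%
                  names(thresholds)),
            all(thresholds$threshold_ppd > 0),
            slope > 0, lapse >= 0, lapse <= 0.05)
  for (ch in unique(thresholds$channel)) {
    g <- thresholds[thresholds$channel == ch, , drop = FALSE]
    g <- g[order(g$eccentricity_deg), , drop = FALSE]
    if (is.unsorted(rev(g$threshold_ppd))) {
      stop("thresholds must be non-increasing with eccentricity (channel ",
           ch, ")")
    }
  }
  structure(list(id = as.character(id), thresholds = thresholds,
                 slope = slope, lapse = lapse),
            class = "simulated_observer")
}

#' True threshold of a simulated observer at a condition
#'
#' @param observer A [simulated_observer()].
#' @param channel,eccentricity_deg Condition to look up.
#' @return Threshold in ppd.
#' @export
observer_threshold <- function(observer, channel, eccentricity_deg) {
  stopifnot(inherits(observer, "simulated_observer"))
  th <- observer$thresholds
  hit <- th$channel == channel & th$eccentricity_deg == eccentricity_deg
  if (!any(hit)) {
    stop("observer ", observer$id, " has no threshold for (", channel, ", ",
         eccentricity_deg, " deg)")
  }
  th$threshold_ppd[which(hit)[1]]
}

#' Sample a population of simulated observers
#'
#' Per-observer thresholds are drawn from `Normal(mu(e), sigma(e))` of the
#' population model for every (channel, eccentricity) knot, truncated at
#' > 0. Draws that violate monotone non-increase with eccentricity within a
#' channel are resampled (up to `max_attempts` per observer/channel).
#'
#' @param n Number of observers (>= 1).
#' @param population A [population_model()]; default the study-calibrated
#'   [default_population()].
#' @param eccentricities Eccentricities to sample at (defaults to the model
#'   knots).
#' @param slope,lapse Psychometric shape shared by all observers.
#' @param seed Integer seed.
#' @param max_attempts Resampling cap for the monotonicity constraint.
#' @return List of [simulated_observer()] objects.
#' @export
sample_population <- function(n, population = default_population(),
                              eccentricities = NULL,
                              slope = 3.5, lapse = 0.02, seed = 1,
                              max_attempts = 100) {
  stopifnot(n >= 1, inherits(population, "population_model"))
  channels <- unique(population$channel)
  if (is.null(eccentricities)) {
    eccentricities <- sort(unique(population$eccentricity_deg))
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("obs%03d", i)
    rows <- list()
    for (ch in channels) {
      ik <- interp_knots(population, ch, eccentricities)
      if (any(ik$mu <= 0)) {
        stop("population mean is not positive for channel ", ch,
             "; cannot draw positive thresholds")
      }
      rng <- local_rng(derive_seed(seed, "pop", id, ch))
      ok <- FALSE
      for (a in seq_len(max_attempts)) {
        draw <- stats::rnorm(length(eccentricities), ik$mu, ik$sigma)
        if (all(draw > 0) && !is.unsorted(rev(draw))) { ok <- TRUE; break }
      }
      rng$restore()
      if (!ok) {
        stop("could not draw positive monotone thresholds for channel ", ch,
             " after ", max_attempts, " attempts")
      }
      rows[[ch]] <- data.frame(channel = ch,
                               eccentricity_deg = eccentricities,
                               threshold_ppd = draw,
                               stringsAsFactors = FALSE)
    }
    out[[i]] <- simulated_observer(id, do.call(rbind, rows),
                                   slope = slope, lapse = lapse)
  }
  out
}

#' Simulate one 2IFC response
#'
#' Bernoulli draw with success probability given by the observer's
#' psychometric function at the tested level ([psychometric_2ifc()] with the
#' observer's true threshold, slope and lapse). Uses the current RNG stream
#' unless `seed` is given.
#'
#' @param observer A [simulated_observer()].
#' @param channel,eccentricity_deg Condition.
#' @param level_ppd Tested level in ppd (> 0).
#' @param seed Optional seed for an isolated draw.
#' @param q Threshold criterion fraction (must match the convention used to
#'   define the observer's thresholds; default midway).
#' @return Logical: response correct?
#' @export
simulate_response <- function(observer, channel, eccentricity_deg, level_ppd,
                              seed = NULL, q = 0.5) {
  stopifnot(level_ppd > 0)
  tau <- observer_threshold(observer, channel, eccentricity_deg)
  p <- psychometric_2ifc(log10(level_ppd), log10(tau), beta = observer$slope,
                         gamma = 0.5, delta = observer$lapse, q = q)
  if (!is.null(seed)) {
    rng <- local_rng(seed)
    on.exit(rng$restore(), add = TRUE)
  }
  stats::runif(1) < p
}

#' Generate a Gabor-like square-wave grating stimulus
#'
#' A square wave of period `period_px` pixels (default 2, the display
#' Nyquist frequency) along the horizontal axis, multiplied by a Gaussian
#' envelope whose standard deviation in pixels is
#' `envelope_sigma_deg * nominal_ppd`. Peak modulation at the envelope
#' centre equals `contrast`. An infinite `envelope_sigma_deg` disables the
#' envelope. The default envelope (sigma 0.5 deg) makes the +/-2 sigma
#' extent of the patch span 2 visual degrees.
#'
#' @param nominal_ppd Display resolution the stimulus is rendered for.
#' @param channel Colour channel label carried in the result.
#' @param contrast Peak modulation in (0, 1], or 0 for a blank stimulus.
#' @param envelope_sigma_deg Envelope SD in degrees (may be `Inf`).
#' @param size_px Image side in pixels (even).
#' @param phase Phase offset of the square wave in radians.
#' @param period_px Square-wave period in pixels (default 2 = Nyquist).
#' @param wave `"square"` (default) or `"sine"`.
#' @return An object of class `stimulus_image`: list with the modulation
#'   `matrix` plus the generation parameters.
#' @export
generate_grating <- function(nominal_ppd, channel = "Ach",
                             contrast = default_contrasts()[[channel]],
                             envelope_sigma_deg = 0.5, size_px = 128,
                             phase = 0, period_px = 2,
                             wave = c("square", "sine")) {
  wave <- match.arg(wave)
  stopifnot(size_px >= 2, size_px %% 2 == 0, contrast >= 0, contrast <= 1,
            nominal_ppd > 0, period_px >= 2)
  x <- (seq_len(size_px) - 0.5)  # pixel centres
  carrier <- sin(2 * pi * x / period_px + phase)
  if (wave == "square") carrier <- sign(carrier)
  img <- matrix(rep(carrier, each = size_px), nrow = size_px) * contrast
  if (is.finite(envelope_sigma_deg)) {
    sigma_px <- envelope_sigma_deg * nominal_ppd
    if (4 * sigma_px > size_px) {
      warning("Gaussian envelope extends beyond the image; clipped")
    }
    c0 <- (size_px + 1) / 2
    g1 <- exp(-((x - c0)^2) / (2 * sigma_px^2))
    img <- img * outer(g1, g1)
  }
  structure(list(matrix = img, nominal_ppd = nominal_ppd, channel = channel,
                 contrast = contrast, envelope_sigma_deg = envelope_sigma_deg,
                 period_px = period_px, wave = wave),
            class = "stimulus_image")
}

#' Reduce effective resolution with a box filter
#'
#' Box-average downsampling by an integer factor `n` followed by
#' nearest-neighbour replication back to the original size, emulating an
#' image upscaled from a display of `n` times lower resolution. Idempotent
#' for a fixed `n`.
#'
#' @param image Numeric matrix (or `stimulus_image`).
#' @param n Integer factor >= 1; both image dimensions must be divisible by
#'   `n`.
#' @return Matrix of the original size with effective resolution reduced by
#'   `n`.
#' @export
resample_box_upscale <- function(image, n) {
  if (inherits(image, "stimulus_image")) image <- image$matrix
  if (length(n) != 1 || n != round(n) || n < 1) {
    stop("`n` must be a single integer >= 1")
  }
  n <- as.integer(n)
  if (n == 1) return(image)
  d <- dim(image)
  if (any(d %% n != 0)) {
    stop("image dimensions must be divisible by n = ", n)
  }
  ri <- (seq_len(d[1]) - 1L) %/% n
  ci <- (seq_len(d[2]) - 1L) %/% n
  # block means via grouped row/column sums
  low <- t(rowsum(t(rowsum(image, ri)), ci)) / (n * n)
  low[ri + 1L, , drop = FALSE][, ci + 1L, drop = FALSE]
}

#' Separable Lanczos resampling
#'
#' Resamples a matrix to `target_size` with a separable Lanczos kernel
#' (`sinc(x) * sinc(x/a)`, support `|x| < a`, default `a = 3`), with the
#' weights of every output pixel normalised to sum to 1 so constant images
#' are preserved exactly.
#'
#' @param image Numeric matrix (or `stimulus_image`).
#' @param target_size Output size, length-1 or `c(rows, cols)`.
#' @param a Kernel support parameter (default 3).
#' @return Resampled matrix.
#' @export
resample_lanczos <- function(image, target_size, a = 3) {
  if (inherits(image, "stimulus_image")) image <- image$matrix
  stopifnot(all(target_size >= 1), a >= 1)
  if (length(target_size) == 1) target_size <- rep(target_size, 2)
  d <- dim(image)
  if (all(d == target_size)) return(image)
  out <- lanczos_1d(image, target_size[1], a)        # rows
  t(lanczos_1d(t(out), target_size[2], a))           # cols
}

lanczos_kernel <- function(x, a) {
  k <- numeric(length(x))
  inside <- abs(x) < a
  xz <- x[inside]
  k[inside] <- ifelse(xz == 0, 1,
                      a * sin(pi * xz) * sin(pi * xz / a) / (pi^2 * xz^2))
  k
}

# Resample along the first dimension to n_out rows.
lanczos_1d <- function(m, n_out, a) {
  n_in <- nrow(m)
  if (n_out == n_in) return(m)
  scale <- n_in / n_out
  # support widens when downscaling (anti-aliasing)
  s <- max(scale, 1)
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    centre <- (i - 0.5) * scale + 0.5  # input coordinate of output pixel i
    j0 <- max(1L, floor(centre - a * s))
    j1 <- min(n_in, ceiling(centre + a * s))
    j <- j0:j1
    w <- lanczos_kernel((j - centre) / s, a)
    sw <- sum(w)
    if (sw == 0) { w <- rep(0, length(j)); w[which.min(abs(j - centre))] <- 1; sw <- 1 }
    W[i, j] <- w / sw
  }
  W %*% m
}

#' Generate a complete synthetic study dataset
#'
#' End-to-end emulation of the study design: sample `n_observers` from the
#' population model, run an interleaved 2IFC/QUEST session per observer and
#' eccentricity over the three colour channels, fit the per-track
#' psychometric functions by maximum likelihood, and flag outliers by
#' modified Z-score per (channel, eccentricity).
#'
#' @param n_observers Number of observers (default 18, the study sample).
#' @param seed Integer seed controlling everything.
#' @param population Generating [population_model()].
#' @param channels,eccentricities Conditions (default the study design).
#' @param config QUEST configuration.
#' @param slope,lapse Observer psychometric shape.
#' @param outlier_cutoff Modified Z-score cutoff (default 3.5).
#' @param ... Further arguments passed to [run_2ifc_session()].
#' @return List with `observers`, `trials` (all trial records) and
#'   `thresholds` (one row per observer x channel x eccentricity with the
#'   MLE threshold, QUEST posterior SD and an `outlier` flag).
#' @export
generate_study_dataset <- function(n_observers = 18, seed = 1,
                                   population = default_population(),
                                   channels = c("Ach", "RG", "YV"),
                                   eccentricities = c(0, 10, 20),
                                   config = quest_config(),
                                   slope = 3.5, lapse = 0.02,
                                   outlier_cutoff = 3.5, ...) {
  observers <- sample_population(n_observers, population,
                                 eccentricities = eccentricities,
                                 slope = slope, lapse = lapse, seed = seed)
  trial_list <- list()
  thr_rows <- list()
  for (obs in observers) {
    for (e in eccentricities) {
      trials <- run_2ifc_session(
        obs, channels = channels, eccentricity_deg = e,
        seed = derive_seed(seed, "trials", obs$id, e), config = config, ...)
      trial_list[[length(trial_list) + 1L]] <-
        cbind(observer_id = obs$id, trials, stringsAsFactors = FALSE)
      ests <- attr(trials, "estimates")
      for (ch in channels) {
        tr <- trials[trials$channel == ch, , drop = FALSE]
        fit <- fit_psychometric_mle(tr, q = config$q)
        thr_rows[[length(thr_rows) + 1L]] <- data.frame(
          observer_id = obs$id, channel = ch, eccentricity_deg = e,
          threshold_ppd = fit$threshold_ppd,
          estimate_sd = ests$sd_log10[ests$channel == ch],
          boundary_flag = fit$boundary_flag,
          stringsAsFactors = FALSE)
      }
    }
  }
  thresholds <- do.call(rbind, thr_rows)
  rownames(thresholds) <- NULL
  thresholds$outlier <- FALSE
  for (ch in channels) {
    for (e in eccentricities) {
      idx <- which(thresholds$channel == ch & thresholds$eccentricity_deg == e)
      if (length(idx) >= 3) {
        thresholds$outlier[idx] <-
          as.logical(detect_outliers_modz(thresholds$threshold_ppd[idx],
                                          cutoff = outlier_cutoff))
      }
    }
  }
  trials <- do.call(rbind, trial_list)
  rownames(trials) <- NULL
  list(observers = observers, trials = trials, thresholds = thresholds)
}
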