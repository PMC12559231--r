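# Configuration, serialisation and the end-to-end pipeline.
#
# File formats: CSV for trial and threshold tables, JSON for fitted
# parameters, YAML or JSON for run configuration, PNG for images.

#' Default run configuration
#'
#' Reproduces the study design: three interleaved colour channels with
#' contrasts 0.96 / 0.23 / 0.89, eccentricities 0 / 10 / 20 degrees, 18
#' observers, QUEST tracks of 30-50 trials with 3 consecutive repeats and a
#' posterior-SD stopping criterion of 0.07 log10 units.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    n_observers = 18,
    channels = c("Ach", "RG", "YV"),
    eccentricities = c(0, 10, 20),
    contrasts = as.list(default_contrasts()),
    quest = list(
      grid_min = 0.3, grid_max = 2.3, grid_step = 0.01,
      prior_mean = log10(60), prior_sd = 0.6,
      beta = 3.5, gamma = 0.5, delta = 0.02, q = 0.5,
      placement = "mean"
    ),
    session = list(
      min_trials = 30, max_trials = 50, stop_sd = 0.07, n_repeats = 3,
      aggregate_repeats = FALSE
    ),
    observer = list(slope = 3.5, lapse = 0.02),
    outlier_cutoff = 3.5
  )
}

merge_config <- function(defaults, user, path = character()) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    where <- if (length(path)) paste0(" under '", paste(path, collapse = "$"), "'") else ""
    stop("unknown config key(s)", where, ": ", paste(unknown, collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]])) stop("config key '", k, "' must be a mapping")
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], c(path, k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads YAML or JSON (by extension), validates every key against
#' [default_config()] (unknown keys are rejected by name) and fills missing
#' keys with the defaults. An empty file yields the full default
#' configuration.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml, .yml or .json")
  }
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config(), user)
  ch_bad <- setdiff(cfg$channels, c("Ach", "RG", "YV"))
  if (length(ch_bad)) stop("unknown channel(s) in config: ",
                           paste(ch_bad, collapse = ", "))
  cfg
}

#' Write / read threshold tables as CSV
#'
#' Schema: `observer_id,channel,eccentricity_deg,threshold_ppd,estimate_sd`.
#' The reader validates the channel vocabulary and positivity.
#'
#' @param df Threshold table.
#' @param path CSV path.
#' @return `read_thresholds_csv` returns the validated data.frame.
#' @export
write_thresholds_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_thresholds_csv
#' @export
read_thresholds_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_threshold_records(df)
}

#' Write / read trial logs as CSV
#'
#' Schema: `track_id,channel,eccentricity_deg,trial_index,repeat_index,
#' level_ppd,correct` (plus `observer_id` when present).
#'
#' @param df Trial table.
#' @param path CSV path.
#' @return `read_trials_csv` returns the data.frame.
#' @export
write_trials_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("track_id", "channel", "eccentricity_deg", "trial_index",
           "repeat_index", "level_ppd", "correct")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("trial CSV missing columns: ",
                         paste(miss, collapse = ", "))
  df
}

#' Serialise fitted channel parameters to JSON
#'
#' @param params_list Named list of [channel_params()] (one per channel).
#' @param path JSON path.
#' @return `read_params_json` returns the named list of channel_params.
#' @export
write_params_json <- function(params_list, path) {
  payload <- lapply(params_list, function(p) {
    list(channel = p$channel, A = p$A, k_e = p$k_e, contrast = p$contrast,
         S0 = p$S0, k_rho = p$k_rho,
         rmse_cpd = if (!is.null(attr(p, "rmse_cpd"))) attr(p, "rmse_cpd") else NA)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(p) {
    channel_params(p$channel, A = p$A, k_e = p$k_e, contrast = p$contrast,
                   S0 = p$S0)
  })
}

#' Write / read an image as PNG
#'
#' @param image Matrix (greyscale) or `height x width x 3` array in [0, 1].
#' @param path PNG path.
#' @return `read_image_png` returns the array.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
  img
}

#' Run the full synthetic-study pipeline and write its artifacts
#'
#' Generate -> simulate -> MLE fit -> outlier rejection -> model and
#' population fits -> report. Writes `trials.csv`, `thresholds.csv`,
#' `params.json`, `population.csv` and `run_log.txt` (seed, config hash,
#' per-stage timing) into `out_dir` (created if missing).
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory results.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  stopifnot(is.list(config), !missing(out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    sprintf("seed: %d", as.integer(config$seed)),
    sprintf("config_hash: %s", config_hash(config)),
    sprintf("generated: R %s", paste(R.version$major, R.version$minor, sep = "."))
  )
  tic <- function() proc.time()[["elapsed"]]

  t0 <- tic()
  qc <- do.call(quest_config, config$quest)
  ds <- generate_study_dataset(
    n_observers = config$n_observers, seed = config$seed,
    channels = config$channels, eccentricities = config$eccentricities,
    config = qc,
    slope = config$observer$slope, lapse = config$observer$lapse,
    outlier_cutoff = config$outlier_cutoff,
    min_trials = config$session$min_trials,
    max_trials = config$session$max_trials,
    stop_sd = config$session$stop_sd,
    n_repeats = config$session$n_repeats,
    aggregate_repeats = config$session$aggregate_repeats)
  log_lines <- c(log_lines, sprintf("stage simulate: %.2f s", tic() - t0))

  t0 <- tic()
  keep <- ds$thresholds[!ds$thresholds$outlier, , drop = FALSE]
  fits <- lapply(stats::setNames(config$channels, config$channels),
                 function(ch) {
    fit_channel_params(keep[keep$channel == ch, , drop = FALSE],
                       contrast = config$contrasts[[ch]])
  })
  pop <- fit_population(keep)
  log_lines <- c(log_lines, sprintf("stage fit: %.2f s", tic() - t0))

  write_trials_csv(ds$trials, file.path(out_dir, "trials.csv"))
  write_thresholds_csv(ds$thresholds, file.path(out_dir, "thresholds.csv"))
  write_params_json(fits, file.path(out_dir, "params.json"))
  utils::write.csv(as.data.frame(unclass(pop)),
                   file.path(out_dir, "population.csv"), row.names = FALSE)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(dataset = ds, fits = fits, population = pop,
                 out_dir = out_dir))
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 131 + code) %% 2147483629
  sprintf("%08x", as.integer(h))
}
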