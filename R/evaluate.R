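# Experiment harnesses: offline reconstruction comparison, encoding
# prediction comparison, closed-loop trial metrics (fraction acquired,
# movement time, Fitts's-law bit rate), and report writing.

#' Compare decoders on offline reconstruction
#'
#' Splits the session with [train_test_split()], fits every requested
#' decoder on the identical training portion, reconstructs the testing
#' portion, and scores each Cartesian axis' position and velocity
#' separately, combining by averaging (SNR averaged in decibels). No output
#' mixing, movement threshold or future offset is applied; the zero-offset
#' tap is read.
#'
#' @param session A `binned_session`.
#' @param variants Decoder variants (see [fit_decoder()]).
#' @param lambda_grid,smooth_accel_window Passed to [fit_decoder()].
#' @param split Optional named list of overrides for
#'   [train_test_split()] (`skip`, `long_train`, `short_train`,
#'   `threshold`), e.g. for short smoke-test sessions.
#' @return Data frame with one row per decoder: mean `cc`, mean `snr_db`,
#'   and the per-series scores as attribute `"per_series"`. The training
#'   fingerprint used by every decoder is attached as attribute
#'   `"train_fingerprint"`.
#' @export
reconstruction_experiment <- function(session,
                                      variants = c("kf", "ukf1", "ukf2"),
                                      lambda_grid = NULL,
                                      smooth_accel_window = 5L,
                                      split = list()) {
  sp <- do.call(train_test_split, c(list(session), split))
  actual <- as.matrix(as.data.frame(sp$test$kinematics)[, c("px", "py", "vx", "vy")])
  fp <- fingerprint(list(bins = sp$train_bins,
                         counts_total = sum(sp$train$spikes$counts)))
  per_series <- list()
  rows <- lapply(variants, function(v) {
    bundle <- fit_decoder(sp$train, v, mode = "offline",
                          lambda_grid = lambda_grid,
                          smooth_accel_window = smooth_accel_window)
    dec <- decode_offline(sp$test, bundle)
    sc <- score_predictions(as.matrix(dec[, c("px", "py", "vx", "vy")]), actual)
    per_series[[v]] <<- sc
    ms <- mean_scores(sc)
    data.frame(decoder = v, cc = ms[["cc"]], snr_db = ms[["snr_db"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "per_series") <- per_series
  attr(out, "train_fingerprint") <- fp
  out
}

#' Compare encoding models by cross-validated prediction
#'
#' Runs [twofold_cv_encoding()] for each requested preset (duplicates are
#' removed deterministically, keeping first occurrences) and stacks the
#' per-unit scores.
#'
#' @param session A `binned_session`.
#' @param presets Character preset names (see [encoding_preset()]).
#' @param lambda_grid Optional ridge grid.
#' @return Data frame `model, unit_id, cc, snr_db`.
#' @export
encoding_experiment <- function(session,
                                presets = c("kf", "ukf1", "ukf1_a",
                                            "ukf1_pvi", "ukf1_t", "ukf1_sh",
                                            "ukf2", "self_history",
                                            "others_history",
                                            "population_history"),
                                lambda_grid = NULL) {
  presets <- presets[!duplicated(presets)]
  do.call(rbind, lapply(presets, function(p) {
    sc <- twofold_cv_encoding(session, p, lambda_grid = lambda_grid)
    cbind(data.frame(model = p, stringsAsFactors = FALSE), sc)
  }))
}

#' Closed-loop trial metrics
#'
#' The fraction acquired counts center and peripheral targets alike.
#' Movement time and Fitts's-law bit rate are computed only for successful
#' center-to-peripheral trials that followed a successful center
#' acquisition, which screens out failures due to user inactivity. Movement
#' time runs from target onset to the start of the final successful hold.
#' The index of difficulty is `ID = log2(D / W + 1)` with `D` the commanded
#' reach distance and `W` the full target diameter (the cursor is logically
#' a point); bit rate is `ID / movement time` and is therefore monotone
#' decreasing in movement time at fixed geometry.
#'
#' @param trials A scored [trial_table()] (e.g. from
#'   [simulate_closed_loop()] or [score_trials()]).
#' @param target_diameter Target diameter `W` (cm).
#' @param dt Bin width (s).
#' @return A `trial_metrics` list: `fraction_acquired`, `movement_times`
#'   (s), `bit_rates` (bits/s), `ids` (bits), `n_trials`, `n_qualifying`.
#'   With no qualifying trials the times and rates are empty and their
#'   means `NA`.
#' @export
trial_metrics <- function(trials, target_diameter = 5, dt = .BIN_WIDTH_DEFAULT) {
  frac <- mean(trials$success)
  prev_ok <- c(FALSE, head(trials$trial_kind, -1) == "center" &
                      head(trials$success, -1))
  qual <- which(trials$trial_kind == "peripheral" & trials$success &
                prev_ok & !is.na(trials$acquire_bin))
  mt <- (trials$acquire_bin[qual] - trials$onset_bin[qual]) * dt
  D <- sqrt(trials$target_x[qual]^2 + trials$target_y[qual]^2)
  id <- log2(D / target_diameter + 1)
  structure(list(fraction_acquired = frac, movement_times = mt,
                 bit_rates = id / mt, ids = id,
                 n_trials = nrow(trials), n_qualifying = length(qual)),
            class = "trial_metrics")
}

#' @export
print.trial_metrics <- function(x, ...) {
  cat(sprintf(paste0("<trial_metrics> %d trials: %.1f%% acquired; ",
                     "%d qualifying center-to-peripheral reaches, mean ",
                     "movement time %.2f s, mean bit rate %.3f bits/s\n"),
              x$n_trials, 100 * x$fraction_acquired, x$n_qualifying,
              if (x$n_qualifying) mean(x$movement_times) else NA,
              if (x$n_qualifying) mean(x$bit_rates) else NA))
  invisible(x)
}

#' Stable fingerprint of a configuration object
#'
#' FNV-1a hash over the serialised object; changes iff the configuration
#' changes.
#'
#' @param x Any R object.
#' @return 8-character hexadecimal string.
#' @export
fingerprint <- function(x) {
  bytes <- serialize(x, NULL, version = 2L)
  bytes <- as.integer(bytes[-seq_len(14L)])  # skip the serialisation header
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% 2147483629
  sprintf("%08x", h)
}

#' Write result tables as TSV and JSON
#'
#' @param tables Named list of data frames.
#' @param dir Output directory.
#' @param config Optional configuration to fingerprint into the report.
#' @param seed Optional seed recorded in the report.
#' @return Path of the JSON report, invisibly.
#' @export
report <- function(tables, dir, config = NULL, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stopifnot(is.list(tables), !is.null(names(tables)))
  for (nm in names(tables)) {
    write_tsv(as.data.frame(tables[[nm]]), file.path(dir, paste0(nm, ".tsv")))
  }
  payload <- list(tables = lapply(tables, as.data.frame),
                  config_fingerprint = if (!is.null(config)) fingerprint(config),
                  seed = seed)
  path <- file.path(dir, "report.json")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Read a JSON report back into tables
#'
#' @param path Path to a `report.json` written by [report()].
#' @return Named list of data frames.
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(payload$tables, as.data.frame)
}
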