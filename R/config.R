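# Run configuration: every analysis constant of the protocol lives here so
# that the default configuration is the zero-override behavior.

#' Default analysis configuration
#'
#' Returns the nested list of tunables used throughout the pipeline. The
#' defaults encode the protocol's analysis constants: a 10 Hz fourth-order
#' zero-lag Butterworth on force; 30-400 Hz band-pass plus 59-61 Hz band-stop
#' on EMG; 10%/90% rise thresholds searched from 0.5 s before to 1 s after
#' step onset; steady-state windows 2-4 s after onset; fall window spanning
#' segment seconds 4-6; MVC mean over 4-8 s; hold-task CV in 1-s windows
#' after the first 5 s; 2-s median-frequency windows.
#'
#' @return nested named list of configuration values.
#' @export
default_config <- function() {
  list(
    force_filter = list(cutoff_hz = 10, order = 4, zero_lag = TRUE,
                        enabled = TRUE),
    emg_filter = list(band_hz = c(30, 400), notch_hz = c(59, 61), order = 4,
                      zero_lag = TRUE, sensor_delay_s = 500e-6),
    exclusion = list(pre_window_s = 0.5, post_window_s = 0.5,
                     pulse_pre_s = 0.25, pulse_post_s = 0.5,
                     baseline_frac = 0.10),
    metrics = list(rise_frac_lo = 0.1, rise_frac_hi = 0.9,
                   rise_window_s = c(-0.5, 1.0), ss_window_s = c(2, 4),
                   fall_window_s = c(4, 6), mvc_window_s = c(4, 8),
                   hold_skip_s = 5, hold_final_s = 10),
    emg = list(window_s = 2, band_hz = c(30, 400),
               estimator = "periodogram"),
    stats = list(alpha = 0.05, n_first_responses = 5,
                 sphericity_correction = "none")
  )
}

# Recursively overlay user values onto defaults, erroring on unknown keys.
merge_config <- function(defaults, user, path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop(sprintf("config key '%s' must be a mapping",
                                   paste(path, collapse = ".")))
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key '%s'",
                 paste(c(path, unknown[1]), collapse = ".")))
  }
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      c(path, key))
    } else {
      value <- user[[key]]
      if (is.list(value)) value <- unlist(value)
      defaults[[key]] <- value
    }
  }
  defaults
}

validate_config <- function(cfg) {
  ff <- cfg$force_filter
  if (ff$cutoff_hz <= 0) stop("force_filter.cutoff_hz must be positive")
  if (ff$order < 1) stop("force_filter.order must be >= 1")
  ef <- cfg$emg_filter
  if (length(ef$band_hz) != 2 || ef$band_hz[1] <= 0 ||
      ef$band_hz[1] >= ef$band_hz[2]) {
    stop("emg_filter.band_hz must be two increasing positive values")
  }
  if (length(ef$notch_hz) != 2 || ef$notch_hz[1] >= ef$notch_hz[2]) {
    stop("emg_filter.notch_hz must be two increasing values")
  }
  mx <- cfg$metrics
  if (!(mx$rise_frac_lo > 0 && mx$rise_frac_lo < mx$rise_frac_hi &&
        mx$rise_frac_hi < 1)) {
    stop("metrics rise fractions must satisfy 0 < lo < hi < 1")
  }
  for (win in c("rise_window_s", "ss_window_s", "fall_window_s",
                "mvc_window_s")) {
    w <- mx[[win]]
    if (length(w) != 2 || w[1] >= w[2]) {
      stop(sprintf("metrics.%s must be two increasing values", win))
    }
  }
  ex <- cfg$exclusion
  if (any(unlist(ex) < 0)) stop("exclusion windows must be non-negative")
  if (ex$baseline_frac >= 1) stop("exclusion.baseline_frac must be < 1")
  if (!cfg$emg$estimator %in% c("periodogram", "welch")) {
    stop("emg.estimator must be 'periodogram' or 'welch'")
  }
  invisible(cfg)
}

#' Read and validate a run configuration
#'
#' Loads a YAML (or JSON, a YAML subset) configuration file, fills every
#' unspecified value from [default_config()], and rejects unknown keys with a
#' message naming the offending key. An empty file yields the full default
#' configuration.
#'
#' @param path path to a YAML/JSON configuration file, or `NULL` for pure
#'   defaults.
#' @return validated nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user)
  }
  validate_config(cfg)
  cfg
}
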