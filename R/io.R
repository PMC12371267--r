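# Format layer: trials travel as a CSV of traces (time_s, force, target)
# plus a JSON sidecar of metadata; EMG as a separate CSV; metric tables as
# deterministic CSVs. Canonical on-disk force unit is BW (body weight in the
# sidecar); Newton storage is supported with an explicit unit flag.

fmt_num <- function(x) sprintf("%.17g", x)

trial_paths <- function(path) {
  base <- sub("\\.csv$", "", path)
  list(csv = paste0(base, ".csv"), meta = paste0(base, ".json"),
       emg = paste0(base, "_emg.csv"))
}

#' Write a trial to disk
#'
#' Writes `<path>.csv` with columns `time_s, force, target` (full double
#' precision), `<path>.json` with all trial metadata (participant,
#' condition, task, repetition, body weight, unit, sample rate, target
#' onsets), and `<path>_emg.csv` when EMG is attached. Write-then-read
#' reproduces the trial exactly.
#'
#' @param trial a `trial_record`.
#' @param path destination path (with or without `.csv`).
#' @param unit `"BW"` (canonical) or `"N"` to store force in Newtons.
#' @return invisibly, the paths written.
#' @export
write_trial <- function(trial, path, unit = c("BW", "N")) {
  unit <- match.arg(unit)
  stopifnot(inherits(trial, "trial_record"))
  p <- trial_paths(path)
  scale <- if (unit == "N") trial$body_weight_n else 1
  df <- data.frame(time_s = fmt_num(trace_times(trial$force)),
                   force = fmt_num(trial$force$values * scale),
                   target = fmt_num(trial$target$values))
  utils::write.csv(df, p$csv, row.names = FALSE, quote = FALSE)
  meta <- list(participant_id = trial$participant_id,
               condition = trial$condition, task = trial$task,
               repetition = trial$repetition,
               body_weight_n = trial$body_weight_n,
               force_unit = unit,
               sample_rate_hz = trial$force$sample_rate_hz,
               t0_s = trial$force$t0_s,
               onsets_s = trial$onsets_s,
               expected_steps = trial$expected_steps,
               order = trial$order,
               has_emg = !is.null(trial$emg))
  jsonlite::write_json(meta, p$meta, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  if (!is.null(trial$emg)) {
    emg_df <- c(list(time_s = fmt_num(trace_times(trial$emg$channels[[1]]))),
                lapply(trial$emg$channels, function(ch) fmt_num(ch$values)))
    utils::write.csv(as.data.frame(emg_df), p$emg, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(p)
}

#' Read a trial from disk
#'
#' Reads the CSV/JSON pair written by [write_trial()], validating the
#' declared columns, uniform time stamps and the force unit flag. Force
#' stored in Newtons is exposed in BW by dividing by the sidecar's body
#' weight.
#'
#' @param path path to the trial (with or without `.csv`).
#' @return a `trial_record`.
#' @export
read_trial <- function(path) {
  p <- trial_paths(path)
  if (!file.exists(p$csv)) stop(sprintf("trial file not found: %s", p$csv))
  if (!file.exists(p$meta)) {
    stop(sprintf("sidecar metadata not found: %s", p$meta))
  }
  df <- utils::read.csv(p$csv)
  for (col in c("time_s", "force", "target")) {
    if (!col %in% names(df)) {
      stop(sprintf("trial CSV is missing column '%s'", col))
    }
  }
  meta <- jsonlite::read_json(p$meta, simplifyVector = TRUE)
  for (key in c("participant_id", "condition", "task", "repetition",
                "body_weight_n", "force_unit", "sample_rate_hz")) {
    if (is.null(meta[[key]])) {
      stop(sprintf("sidecar is missing key '%s'", key))
    }
  }
  fs <- meta$sample_rate_hz
  dt <- diff(df$time_s)
  if (length(dt) > 0 && any(abs(dt - 1 / fs) > 1e-6 / fs)) {
    stop("time_s is not uniformly sampled at the declared rate")
  }
  if (!meta$force_unit %in% c("BW", "N")) {
    stop("force_unit flag must be 'BW' or 'N'")
  }
  scale <- if (meta$force_unit == "N") 1 / meta$body_weight_n else 1
  t0 <- if (length(df$time_s) > 0) df$time_s[1] else 0
  force <- sampled_trace(df$force * scale, fs, t0)
  target <- sampled_trace(df$target, fs, t0)
  emg <- NULL
  if (isTRUE(meta$has_emg) && file.exists(p$emg)) {
    emg_df <- utils::read.csv(p$emg)
    ch_names <- setdiff(names(emg_df), "time_s")
    dt_e <- diff(emg_df$time_s)
    fs_e <- 1 / stats::median(dt_e)
    chans <- lapply(emg_df[ch_names], function(v) {
      sampled_trace(v, fs_e, emg_df$time_s[1])
    })
    emg <- emg_channel_set(chans)
  }
  trial_record(meta$participant_id, meta$condition, meta$task,
               meta$repetition, meta$body_weight_n, force, target,
               onsets_s = if (length(meta$onsets_s) > 0) meta$onsets_s,
               expected_steps = meta$expected_steps %||% 0L,
               emg = emg, order = meta$order %||% NA_integer_)
}

METRICS_COLUMNS <- c("participant_id", "condition", "task", "repetition",
                     "order", "step_index", "rise_time_ms", "bandwidth_hz",
                     "fall_time_ms", "overshoot_pct",
                     "steady_state_error_pct",
                     "steady_state_variability_pct", "excluded",
                     "exclusion_reasons")

#' Write a per-response metrics table as CSV
#'
#' One row per (participant, condition, task, repetition, step index) with
#' all step-response characteristics and exclusion flags, in a stable column
#' order; excluded rows keep their identity columns with metric fields
#' empty. Deterministic: identical input produces byte-identical output.
#'
#' @param rows data.frame of metric rows (as produced by [step_metrics()]).
#' @param path output CSV path.
#' @param blank_excluded blank out metric fields on excluded rows.
#' @return invisibly, `path`.
#' @export
write_metrics_table <- function(rows, path, blank_excluded = TRUE) {
  if (is.null(rows) || nrow(rows) == 0) {
    rows <- as.data.frame(stats::setNames(
      replicate(length(METRICS_COLUMNS), character(0), simplify = FALSE),
      METRICS_COLUMNS))
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  for (col in setdiff(METRICS_COLUMNS, names(rows))) rows[[col]] <- NA
  rows <- rows[, METRICS_COLUMNS]
  metric_cols <- c("rise_time_ms", "bandwidth_hz", "fall_time_ms",
                   "overshoot_pct", "steady_state_error_pct",
                   "steady_state_variability_pct")
  if (blank_excluded && any(rows$excluded)) {
    rows[rows$excluded, metric_cols] <- NA
  }
  for (col in metric_cols) {
    rows[[col]] <- ifelse(is.na(rows[[col]]), "",
                          sprintf("%.6f", rows[[col]]))
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
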