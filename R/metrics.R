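# Response characteristics and fatigue measures. All step metrics are pure
# functions of (segment, config); window boundaries are half-open
# [start, end) on the segment clock, so metrics are invariant to shifting
# the segment's time origin.

# First interpolated up-crossing of thr within [from, to); NA if none.
first_crossing <- function(trace, thr, from, to, direction = "up") {
  tc <- crossing_times(trace, thr, direction)
  eps <- 0.25 / trace$sample_rate_hz
  tc <- tc[tc >= from - eps & tc < to - eps]
  if (length(tc) == 0) NA_real_ else tc[1]
}

#' 10-90% rise time of a step response
#'
#' Time for the force to travel from 10% to 90% of the step amplitude
#' (thresholds `baseline + 0.1*step` and `baseline + 0.9*step`), searched
#' from 0.5 s before the target step-up to 1 s after it. Crossings are the
#' first threshold crossings, located by linear interpolation between
#' samples.
#'
#' @param segment a `response_segment`.
#' @param config configuration (uses `metrics` block).
#' @return list with `value_ms` (NA when a threshold is never crossed in the
#'   window) and `ok`.
#' @export
rise_time <- function(segment, config = default_config()) {
  mx <- config$metrics
  onset <- segment$onset_s
  from <- onset + mx$rise_window_s[1]
  to <- onset + mx$rise_window_s[2]
  th_lo <- segment$baseline_bw + mx$rise_frac_lo * segment$step_size_bw
  th_hi <- segment$baseline_bw + mx$rise_frac_hi * segment$step_size_bw
  t_lo <- first_crossing(segment$force, th_lo, from, to)
  t_hi <- first_crossing(segment$force, th_hi, from, to)
  if (is.na(t_lo) || is.na(t_hi) || t_hi < t_lo) {
    return(list(value_ms = NA_real_, ok = FALSE))
  }
  list(value_ms = 1000 * (t_hi - t_lo), ok = TRUE)
}

#' Bandwidth from rise time
#'
#' The trackable-frequency approximation `0.35 / rise time` (rise time in
#' seconds, bandwidth in Hz). Because bandwidth is computed per response and
#' then averaged, a mean bandwidth is generally not `0.35 /` the mean rise
#' time.
#'
#' @param rise_time_ms rise time in milliseconds (> 0).
#' @return bandwidth in Hz, or NA if the rise time is missing or zero.
#' @export
bandwidth <- function(rise_time_ms) {
  ifelse(is.na(rise_time_ms) | rise_time_ms <= 0, NA_real_,
         0.35 / (rise_time_ms / 1000))
}

#' 90-10% fall time of a step response
#'
#' Time for the force to fall from 90% back to 10% of the step amplitude.
#' For step segments the search window is segment seconds 4-6 (bracketing
#' the step-down at second 5); for pulse segments it runs from the pulse end
#' to the segment end. The 10% crossing is the first one after the 90%
#' down-crossing.
#'
#' @inheritParams rise_time
#' @return list with `value_ms` and `ok`.
#' @export
fall_time <- function(segment, config = default_config()) {
  mx <- config$metrics
  if (segment$task == "STEP") {
    from <- segment$force$t0_s + mx$fall_window_s[1]
    to <- segment$force$t0_s + mx$fall_window_s[2]
  } else {
    from <- segment$onset_s + segment$on_duration_s
    to <- segment$force$t0_s + trace_duration(segment$force)
  }
  th_lo <- segment$baseline_bw + mx$rise_frac_lo * segment$step_size_bw
  th_hi <- segment$baseline_bw + mx$rise_frac_hi * segment$step_size_bw
  t_hi <- first_crossing(segment$force, th_hi, from, to, "down")
  if (is.na(t_hi)) return(list(value_ms = NA_real_, ok = FALSE))
  t_lo <- first_crossing(segment$force, th_lo, t_hi, to, "down")
  if (is.na(t_lo)) return(list(value_ms = NA_real_, ok = FALSE))
  list(value_ms = 1000 * (t_lo - t_hi), ok = TRUE)
}

#' Overshoot of a step response
#'
#' `100 * (peak - upper target) / step size`, the peak taken from 0.5 s
#' before the step-up to 1 s after it. Signed: a peak below the target gives
#' a negative overshoot (no clamping, so means are unbiased).
#'
#' @inheritParams rise_time
#' @return list with `value_pct` and `ok`.
#' @export
overshoot <- function(segment, config = default_config()) {
  mx <- config$metrics
  onset <- segment$onset_s
  w <- window_idx(segment$force, onset + mx$rise_window_s[1],
                  onset + mx$rise_window_s[2])
  if (length(w) == 0) return(list(value_pct = NA_real_, ok = FALSE))
  upper <- segment$baseline_bw + segment$step_size_bw
  pk <- max(segment$force$values[w])
  list(value_pct = 100 * (pk - upper) / segment$step_size_bw, ok = TRUE)
}

#' Steady-state error of a step response
#'
#' `100 * |mean(force) - upper target| / upper target` over the settled
#' window 2-4 s after the step onset.
#'
#' @inheritParams rise_time
#' @return list with `value_pct` and `ok`.
#' @export
steady_state_error <- function(segment, config = default_config()) {
  mx <- config$metrics
  onset <- segment$onset_s
  w <- window_idx(segment$force, onset + mx$ss_window_s[1],
                  onset + mx$ss_window_s[2])
  if (length(w) == 0) return(list(value_pct = NA_real_, ok = FALSE))
  upper <- segment$baseline_bw + segment$step_size_bw
  m <- mean(segment$force$values[w])
  list(value_pct = 100 * abs(m - upper) / upper, ok = TRUE)
}

#' Steady-state variability of a step response
#'
#' Coefficient of variation `100 * SD / mean` of the force over the settled
#' window 2-4 s after the step onset.
#'
#' @inheritParams rise_time
#' @return list with `value_pct` and `ok`.
#' @export
steady_state_variability <- function(segment, config = default_config()) {
  mx <- config$metrics
  onset <- segment$onset_s
  w <- window_idx(segment$force, onset + mx$ss_window_s[1],
                  onset + mx$ss_window_s[2])
  if (length(w) == 0) return(list(value_pct = NA_real_, ok = FALSE))
  v <- segment$force$values[w]
  m <- mean(v)
  if (m == 0) return(list(value_pct = NA_real_, ok = FALSE))
  list(value_pct = 100 * stats::sd(v) / m, ok = TRUE)
}

#' All step-response characteristics of one segment
#'
#' Computes rise time, bandwidth, fall time, overshoot, steady-state error
#' and steady-state variability, plus the segment's exclusion decision. For
#' pulse segments only the responsiveness metrics (rise, bandwidth, fall)
#' are evaluated.
#'
#' @inheritParams rise_time
#' @return one-row data.frame.
#' @export
step_metrics <- function(segment, config = default_config()) {
  rt <- rise_time(segment, config)
  ft <- fall_time(segment, config)
  if (segment$task == "STEP") {
    ov <- overshoot(segment, config)
    se <- steady_state_error(segment, config)
    sv <- steady_state_variability(segment, config)
    flags <- apply_step_exclusions(segment, config)
  } else {
    ov <- se <- sv <- list(value_pct = NA_real_, ok = FALSE)
    flags <- apply_pulse_exclusions(segment, config)
  }
  meta <- segment$meta
  data.frame(
    participant_id = meta$participant_id %||% NA_character_,
    condition = meta$condition %||% NA_character_,
    task = segment$task,
    repetition = meta$repetition %||% NA_integer_,
    order = meta$order %||% NA_integer_,
    step_index = segment$step_index,
    rise_time_ms = rt$value_ms,
    bandwidth_hz = bandwidth(rt$value_ms),
    fall_time_ms = ft$value_ms,
    overshoot_pct = ov$value_pct,
    steady_state_error_pct = se$value_pct,
    steady_state_variability_pct = sv$value_pct,
    excluded = flags$excluded,
    exclusion_reasons = paste(flags$reasons, collapse = ";"),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean MVC force
#'
#' Mean force over the 4-8 s window of a maximal-effort trial.
#'
#' @param trial an MVC `trial_record` (or any trial of at least 8 s).
#' @param config configuration (uses `metrics$mvc_window_s`).
#' @return list with `mean_force_bw` and `ok`.
#' @export
mvc_mean <- function(trial, config = default_config()) {
  stopifnot(inherits(trial, "trial_record"))
  w <- config$metrics$mvc_window_s + trial$force$t0_s
  if (trace_duration(trial$force) < config$metrics$mvc_window_s[2]) {
    return(list(mean_force_bw = NA_real_, ok = FALSE))
  }
  idx <- window_idx(trial$force, w[1], w[2])
  list(mean_force_bw = mean(trial$force$values[idx]), ok = TRUE)
}

#' Force variability through a Hold trial
#'
#' Coefficient of variation (`100 * SD / mean`) of the force in contiguous
#' 1-s windows, starting after the first 5 s (the target-acquisition phase),
#' plus the mean over the last 10 windows — the hold's closing-variability
#' summary. Partial trailing windows are dropped.
#'
#' @param trial a HOLD `trial_record` (>= 15 s).
#' @param config configuration (uses `metrics$hold_skip_s`,
#'   `metrics$hold_final_s`).
#' @return list with `cv_per_second` (one CV% per window),
#'   `final10_mean_cv_pct` and `ok`.
#' @export
hold_variability <- function(trial, config = default_config()) {
  stopifnot(inherits(trial, "trial_record"))
  skip <- config$metrics$hold_skip_s
  n_final <- config$metrics$hold_final_s
  dur <- trace_duration(trial$force)
  if (dur < skip + 10) {
    return(list(cv_per_second = numeric(0), final10_mean_cv_pct = NA_real_,
                ok = FALSE))
  }
  n_seg <- floor(dur) - skip
  t0 <- trial$force$t0_s
  cvs <- vapply(seq_len(n_seg), function(i) {
    idx <- window_idx(trial$force, t0 + skip + i - 1, t0 + skip + i)
    v <- trial$force$values[idx]
    100 * stats::sd(v) / mean(v)
  }, numeric(1))
  final <- mean(utils::tail(cvs, n_final))
  list(cv_per_second = cvs, final10_mean_cv_pct = final, ok = TRUE)
}
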