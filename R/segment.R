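# Cut Step and Pulse trials into onset-aligned response segments and apply
# the response exclusion criteria. Onsets always come from the target
# waveform metadata, never from the force signal.

#' An onset-aligned excerpt of a trial around one step or pulse
#'
#' Step segments span 6 s (1 s before step-up to 1 s after step-down);
#' pulse segments span 3 s (1.5 s either side). Segment clocks start at 0,
#' placing the onset at second 1 (STEP) or 1.5 (PULSE).
#'
#' @param force,target `sampled_trace` excerpts on the segment clock.
#' @param onset_s target step-up time on the segment clock.
#' @param on_duration_s time the target stays at its upper value.
#' @param baseline_bw,step_size_bw lower target value and step amplitude.
#' @param step_index 1-based index of the step within its trial.
#' @param task `"STEP"` or `"PULSE"`.
#' @param meta named list of trial metadata carried along.
#' @return an object of class `response_segment`.
#' @export
response_segment <- function(force, target, onset_s, on_duration_s,
                             baseline_bw, step_size_bw, step_index, task,
                             meta = list()) {
  if (step_size_bw <= 0) stop("step_size_bw must be positive")
  structure(list(force = force, target = target, onset_s = onset_s,
                 on_duration_s = on_duration_s, baseline_bw = baseline_bw,
                 step_size_bw = step_size_bw,
                 step_index = as.integer(step_index), task = task,
                 meta = meta),
            class = "response_segment")
}

#' @export
print.response_segment <- function(x, ...) {
  cat(sprintf("<response_segment> %s step %d, onset %.3g s, %.3g s window\n",
              x$task, x$step_index, x$onset_s, trace_duration(x$force)))
  invisible(x)
}

segment_trial <- function(trial, pre_s, post_s, task) {
  stopifnot(inherits(trial, "trial_record"))
  if (trial$task != task) {
    stop(sprintf("expected a %s trial, got %s", task, trial$task))
  }
  onsets <- trial$onsets_s
  expected <- trial$expected_steps
  if (is.null(onsets) || length(onsets) < expected) {
    stop(sprintf("found %d of %d target steps (onsets: %s)",
                 length(onsets), expected,
                 if (length(onsets)) paste(signif(onsets, 4), collapse = ", ")
                 else "none"))
  }
  upper <- max(trial$target$values)
  baseline <- min(trial$target$values)
  dur <- trace_duration(trial$force)
  on_s <- if (length(onsets) > 1) {
    # on-duration from the target itself: samples at the upper value per step
    sum(trial$target$values > (baseline + upper) / 2) /
      trial$target$sample_rate_hz / length(onsets)
  } else {
    sum(trial$target$values > (baseline + upper) / 2) /
      trial$target$sample_rate_hz
  }
  meta <- list(participant_id = trial$participant_id,
               condition = trial$condition, task = trial$task,
               repetition = trial$repetition, order = trial$order)
  lapply(seq_along(onsets), function(i) {
    t0 <- onsets[i] - pre_s
    t1 <- onsets[i] + post_s
    if (t0 < -1e-9 || t1 > dur + 1e-9) {
      stop(sprintf("segment window [%g, %g] s falls outside the trial", t0, t1))
    }
    response_segment(
      force = trace_window(trial$force, t0, t1, retime = TRUE),
      target = trace_window(trial$target, t0, t1, retime = TRUE),
      onset_s = pre_s, on_duration_s = on_s, baseline_bw = baseline,
      step_size_bw = upper - baseline, step_index = i, task = task,
      meta = meta)
  })
}

#' Segment a Step trial into onset-aligned step responses
#'
#' One 6-s segment per target step (1 s before the step-up to 1 s after the
#' step-down), windows anchored to the target onsets recorded in the trial
#' metadata. Errors if fewer steps than programmed are present, listing the
#' onsets that were found.
#'
#' @param trial a STEP `trial_record`.
#' @return list of `response_segment` (one per step).
#' @export
segment_step_task <- function(trial) {
  segment_trial(trial, pre_s = 1, post_s = 5, task = "STEP")
}

#' Segment a Pulse trial into onset-aligned pulse responses
#'
#' One 3-s segment per pulse (1.5 s before the step-up to 1.5 s after the
#' step-down).
#'
#' @param trial a PULSE `trial_record`.
#' @return list of `response_segment`.
#' @export
segment_pulse_task <- function(trial) {
  segment_trial(trial, pre_s = 1.5, post_s = 1.5, task = "PULSE")
}

# Interpolated times (segment clock) at which v crosses thr going up/down.
# Crossing between samples i-1 and i is placed by linear interpolation.
crossing_times <- function(trace, thr, direction = c("up", "down")) {
  direction <- match.arg(direction)
  v <- trace$values
  t <- trace_times(trace)
  if (direction == "up") {
    idx <- which(v[-1] >= thr & v[-length(v)] < thr) + 1L
  } else {
    idx <- which(v[-1] < thr & v[-length(v)] >= thr) + 1L
  }
  if (length(idx) == 0) return(numeric(0))
  frac <- (thr - v[idx - 1]) / (v[idx] - v[idx - 1])
  t[idx - 1] + frac * (t[idx] - t[idx - 1])
}

#' Exclusion flags for one response segment
#'
#' Step criteria: the response (1) steps up half a second or more before the
#' target does (`early_rise`), (2) has not begun to step up within half a
#' second after the target steps up (`no_rise`), (3) already sits above 10%
#' of the step during the half second leading up to the step-up
#' (`elevated_baseline`), or (4) steps down one second or more before the
#' target steps down (`early_fall`). Pulse criteria: the response rises a
#' quarter second or more before the pulse (`early_rise`) or has not fallen
#' back below 10% of the step until more than half a second after the pulse
#' ends (`late_fall`). "Steps up" / "steps down" are operationalized as the
#' first/last crossing of baseline + 10% of the step size, the same
#' threshold family the rise-time metric uses; windows are anchored to the
#' target transitions with closed endpoints.
#'
#' @param segment a `response_segment`.
#' @param config configuration (uses `exclusion` block).
#' @return list with `excluded` (logical) and `reasons` (character vector).
#' @export
apply_step_exclusions <- function(segment, config = default_config()) {
  stopifnot(inherits(segment, "response_segment"))
  ex <- config$exclusion
  onset <- segment$onset_s
  th10 <- segment$baseline_bw + ex$baseline_frac * segment$step_size_bw
  reasons <- character(0)
  ups <- crossing_times(segment$force, th10, "up")
  pre_ups <- ups[ups <= onset]
  if (length(pre_ups) > 0 && pre_ups[1] <= onset - ex$pre_window_s) {
    reasons <- c(reasons, "early_rise")
  }
  w <- window_idx(segment$force, onset, onset + ex$post_window_s +
                    1 / segment$force$sample_rate_hz)
  if (max(segment$force$values[w]) < th10) {
    reasons <- c(reasons, "no_rise")
  }
  pre_w <- window_idx(segment$force, onset - ex$pre_window_s, onset)
  if (mean(segment$force$values[pre_w]) > th10) {
    reasons <- c(reasons, "elevated_baseline")
  }
  t_down <- onset + segment$on_duration_s
  post_ups <- ups[ups > onset - ex$pre_window_s]
  if (length(post_ups) > 0) {
    downs <- crossing_times(segment$force, th10, "down")
    downs <- downs[downs > post_ups[1] & downs <= t_down - 1]
    if (length(downs) > 0) reasons <- c(reasons, "early_fall")
  }
  list(excluded = length(reasons) > 0, reasons = reasons)
}

#' @rdname apply_step_exclusions
#' @export
apply_pulse_exclusions <- function(segment, config = default_config()) {
  stopifnot(inherits(segment, "response_segment"))
  ex <- config$exclusion
  onset <- segment$onset_s
  th10 <- segment$baseline_bw + ex$baseline_frac * segment$step_size_bw
  reasons <- character(0)
  ups <- crossing_times(segment$force, th10, "up")
  pre_ups <- ups[ups <= onset]
  if (length(pre_ups) > 0 && pre_ups[1] <= onset - ex$pulse_pre_s) {
    reasons <- c(reasons, "early_rise")
  }
  t_end <- onset + segment$on_duration_s
  rose <- any(segment$force$values[trace_times(segment$force) > onset] >= th10)
  if (rose) {
    downs <- crossing_times(segment$force, th10, "down")
    downs <- downs[downs > onset]
    t_fall <- if (length(downs) > 0) downs[length(downs)] else Inf
    if (t_fall > t_end + ex$pulse_post_s) {
      reasons <- c(reasons, "late_fall")
    }
  }
  list(excluded = length(reasons) > 0, reasons = reasons)
}
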