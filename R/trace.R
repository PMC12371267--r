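# Core signal containers shared by every stage of the pipeline.

#' Experimental condition labels, in protocol order
#' @export
CONDITIONS <- c("Training", "PreFatigue", "Fatigue1", "Fatigue2", "Fatigue3")

#' Task kinds
#' @export
TASKS <- c("MVC", "HOLD", "STEP", "PULSE")

#' Recorded EMG muscles (right leg), in channel order
#' @export
EMG_MUSCLES <- c("vastus_medialis", "vastus_lateralis", "rectus_femoris",
                 "biceps_femoris", "gastroc_medialis", "gastroc_lateralis")

#' Uniformly sampled scalar time series
#'
#' The universal signal carrier: a numeric vector plus its sampling rate and
#' the time of the first sample. Sample `i` represents time
#' `t0_s + (i - 1) / sample_rate_hz`.
#'
#' @param values numeric vector of finite samples.
#' @param sample_rate_hz sampling rate in Hz (> 0).
#' @param t0_s time of the first sample, seconds.
#' @return an object of class `sampled_trace`.
#' @export
sampled_trace <- function(values, sample_rate_hz, t0_s = 0) {
  values <- as.numeric(values)
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("sample_rate_hz must be a single positive number")
  }
  if (length(values) == 0) stop("values must be non-empty")
  if (!all(is.finite(values))) stop("values must be finite")
  structure(list(values = values, sample_rate_hz = sample_rate_hz,
                 t0_s = as.numeric(t0_s)),
            class = "sampled_trace")
}

#' @export
print.sampled_trace <- function(x, ...) {
  cat(sprintf("<sampled_trace> %d samples @ %g Hz, t = [%g, %g] s\n",
              length(x$values), x$sample_rate_hz, x$t0_s,
              x$t0_s + (length(x$values) - 1) / x$sample_rate_hz))
  invisible(x)
}

#' @export
length.sampled_trace <- function(x) length(x$values)

#' Sample times of a trace
#' @param x a `sampled_trace`.
#' @return numeric vector of times in seconds.
#' @export
trace_times <- function(x) {
  x$t0_s + (seq_along(x$values) - 1) / x$sample_rate_hz
}

#' Duration of a trace in seconds (n / fs)
#' @param x a `sampled_trace`.
#' @export
trace_duration <- function(x) length(x$values) / x$sample_rate_hz

# Indices of samples with time in the half-open window [from, to).
# A small epsilon absorbs floating-point jitter at the endpoints.
window_idx <- function(x, from, to) {
  t <- trace_times(x)
  eps <- 0.25 / x$sample_rate_hz
  which(t >= from - eps & t < to - eps)
}

#' Extract the samples of a trace falling in a half-open time window
#'
#' @param x a `sampled_trace`.
#' @param from,to window `[from, to)` in the trace's own time, seconds.
#' @param retime if `TRUE` the result's clock starts at 0 at `from`.
#' @return a `sampled_trace`.
#' @export
trace_window <- function(x, from, to, retime = FALSE) {
  idx <- window_idx(x, from, to)
  if (length(idx) == 0) stop(sprintf("window [%g, %g) is empty", from, to))
  t_first <- x$t0_s + (idx[1] - 1) / x$sample_rate_hz
  sampled_trace(x$values[idx], x$sample_rate_hz,
                t0_s = if (retime) t_first - from else t_first)
}

#' Set of synchronously recorded EMG channels
#'
#' @param channels named list of `sampled_trace` objects (equal lengths,
#'   common sampling rate); names are muscle identifiers.
#' @return an object of class `emg_channel_set`.
#' @export
emg_channel_set <- function(channels) {
  if (length(channels) == 0 || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop("channels must be a non-empty named list")
  }
  ns <- vapply(channels, function(ch) length(ch$values), integer(1))
  if (length(unique(ns)) != 1) stop("EMG channels must have equal lengths")
  fs <- vapply(channels, function(ch) ch$sample_rate_hz, numeric(1))
  if (length(unique(fs)) != 1) stop("EMG channels must share a sample rate")
  structure(list(channels = channels, sample_rate_hz = fs[[1]]),
            class = "emg_channel_set")
}

#' @export
print.emg_channel_set <- function(x, ...) {
  cat(sprintf("<emg_channel_set> %d channels @ %g Hz (%s)\n",
              length(x$channels), x$sample_rate_hz,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' One execution of a force-control task
#'
#' Bundles the measured force trace, the commanded target trace and the
#' trial's protocol metadata. Force is stored normalized to body weight (BW).
#'
#' @param participant_id participant label.
#' @param condition one of [CONDITIONS].
#' @param task one of [TASKS].
#' @param repetition 1-based ordinal of this trial within (condition, task).
#' @param body_weight_n participant body weight in Newtons (> 0).
#' @param force `sampled_trace` of vertical force in BW.
#' @param target `sampled_trace` of the displayed target in BW; must match
#'   `force` in rate and length.
#' @param onsets_s times (trial clock, seconds) at which the target steps up;
#'   `NULL` for MVC/HOLD.
#' @param expected_steps number of target steps the task was programmed with.
#' @param emg optional `emg_channel_set`.
#' @param order ordinal position of the trial within the whole session.
#' @return an object of class `trial_record`.
#' @export
trial_record <- function(participant_id, condition, task, repetition,
                         body_weight_n, force, target, onsets_s = NULL,
                         expected_steps = if (is.null(onsets_s)) 0L else length(onsets_s),
                         emg = NULL, order = NA_integer_) {
  condition <- match.arg(condition, CONDITIONS)
  task <- match.arg(task, TASKS)
  if (!is.numeric(body_weight_n) || body_weight_n <= 0) {
    stop("body_weight_n must be positive")
  }
  stopifnot(inherits(force, "sampled_trace"), inherits(target, "sampled_trace"))
  if (force$sample_rate_hz != target$sample_rate_hz ||
      length(force$values) != length(target$values)) {
    stop("force and target must share sample rate and length")
  }
  structure(list(participant_id = as.character(participant_id),
                 condition = condition, task = task,
                 repetition = as.integer(repetition),
                 body_weight_n = as.numeric(body_weight_n),
                 force = force, target = target,
                 onsets_s = onsets_s,
                 expected_steps = as.integer(expected_steps),
                 emg = emg, order = as.integer(order)),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> %s / %s / %s rep %d (%.1f s @ %g Hz%s)\n",
              x$participant_id, x$condition, x$task, x$repetition,
              trace_duration(x$force), x$force$sample_rate_hz,
              if (is.null(x$emg)) "" else ", with EMG"))
  invisible(x)
}
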