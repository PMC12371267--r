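# Filtering and alignment. Zero-lag (forward-backward) Butterworth filters
# with reflective padding so that settling transients stay outside the first
# analysis window.

# Apply a Butterworth filter to a numeric vector. With zero_lag the signal is
# reflection-padded by `pad` samples at both ends, filtered forward and
# backward, and unpadded; the magnitude response is squared and the phase is
# zero.
butter_apply <- function(x, fs, type, cutoffs_hz, order, zero_lag = TRUE) {
  nyq <- fs / 2
  if (any(cutoffs_hz >= nyq)) {
    stop(sprintf("cutoff %g Hz is not below the Nyquist frequency %g Hz",
                 max(cutoffs_hz), nyq))
  }
  if (any(cutoffs_hz <= 0)) stop("cutoff frequencies must be positive")
  if (order < 1) stop("filter order must be >= 1")
  bf <- signal::butter(order, cutoffs_hz / nyq, type = type)
  n <- length(x)
  if (!zero_lag) {
    return(as.numeric(signal::filter(bf, x)))
  }
  # remove the leading value before filtering so the zero initial state
  # matches the signal (restored afterwards through the filter's DC gain),
  # and reflection-pad by ~10 settling lengths of the slowest edge so the
  # start-up transient has fully decayed before the retained samples
  dc_gain <- (sum(bf$b) / sum(bf$a))^2
  x0 <- x[1]
  x <- x - x0
  pad <- min(n - 1, ceiling(10 * fs / min(cutoffs_hz)))
  if (pad > 0) {
    head_ref <- 2 * x[1] - x[seq(pad + 1, 2)]
    tail_ref <- 2 * x[n] - x[seq(n - 1, n - pad)]
    xp <- c(head_ref, x, tail_ref)
  } else {
    xp <- x
  }
  y <- as.numeric(signal::filter(bf, xp))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[seq(pad + 1, pad + n)] + x0 * dc_gain
}

#' Low-pass filter a force trace
#'
#' Fourth-order 10 Hz Butterworth by default, the same filter used for the
#' on-screen feedback signal; applied zero-lag (forward-backward) so that
#' response-timing metrics are not biased by group delay.
#'
#' @param trace a `sampled_trace` of force.
#' @param cutoff_hz low-pass cutoff in Hz (must be below Nyquist).
#' @param order filter order (of one pass).
#' @param zero_lag apply forward-backward for zero phase.
#' @return filtered `sampled_trace`.
#' @export
filter_force <- function(trace, cutoff_hz = 10, order = 4, zero_lag = TRUE) {
  stopifnot(inherits(trace, "sampled_trace"))
  y <- butter_apply(trace$values, trace$sample_rate_hz, "low", cutoff_hz,
                    order, zero_lag)
  sampled_trace(y, trace$sample_rate_hz, trace$t0_s)
}

#' Band-pass and notch filter an EMG channel set
#'
#' Applies the surface-EMG conditioning chain: 30-400 Hz band-pass followed
#' by a 59-61 Hz band-stop (mains residual), both fourth-order zero-lag
#' Butterworth filters.
#'
#' @param emg an `emg_channel_set` sampled at 2000 Hz.
#' @param band_hz band-pass edges, Hz.
#' @param notch_hz band-stop edges, Hz.
#' @param order filter order per pass.
#' @param allow_any_rate permit sample rates other than 2000 Hz.
#' @return filtered `emg_channel_set`.
#' @export
filter_emg <- function(emg, band_hz = c(30, 400), notch_hz = c(59, 61),
                       order = 4, allow_any_rate = FALSE) {
  stopifnot(inherits(emg, "emg_channel_set"))
  if (!allow_any_rate && emg$sample_rate_hz != 2000) {
    stop("EMG sample rate is not 2000 Hz; set allow_any_rate = TRUE to filter anyway")
  }
  fs <- emg$sample_rate_hz
  chans <- lapply(emg$channels, function(ch) {
    y <- butter_apply(ch$values, fs, "pass", band_hz, order, TRUE)
    y <- butter_apply(y, fs, "stop", notch_hz, order, TRUE)
    sampled_trace(y, fs, ch$t0_s)
  })
  emg_channel_set(chans)
}

#' Correct the EMG inter-sensor transmission delay
#'
#' Wireless EMG sensors report samples a fixed transmission delay after the
#' underlying muscle activity; this shifts each channel back onto the force
#' clock by linear interpolation. Length is preserved (edge values held).
#'
#' @param emg an `emg_channel_set`.
#' @param delay_s transmission delay in seconds; a scalar applied to every
#'   channel or one value per channel.
#' @return corrected `emg_channel_set`.
#' @export
correct_sensor_delay <- function(emg, delay_s = 500e-6) {
  stopifnot(inherits(emg, "emg_channel_set"))
  nch <- length(emg$channels)
  delay_s <- rep_len(delay_s, nch)
  dur <- trace_duration(emg$channels[[1]])
  if (any(abs(delay_s) >= dur)) stop("delay exceeds trace duration")
  corrected <- mapply(function(ch, d) {
    if (d == 0) return(ch)
    t <- trace_times(ch)
    # sample recorded at t was produced at t - d: evaluate record at t + d
    y <- stats::approx(t, ch$values, xout = t + d, rule = 2)$y
    sampled_trace(y, ch$sample_rate_hz, ch$t0_s)
  }, emg$channels, delay_s, SIMPLIFY = FALSE)
  names(corrected) <- names(emg$channels)
  emg_channel_set(corrected)
}

#' Preprocess a trial's force signal per configuration
#'
#' @param trial a `trial_record`.
#' @param config configuration list from [default_config()].
#' @return the trial with its force trace filtered (unless disabled).
#' @export
preprocess_trial <- function(trial, config = default_config()) {
  ff <- config$force_filter
  if (isTRUE(ff$enabled)) {
    trial$force <- filter_force(trial$force, ff$cutoff_hz, ff$order,
                                ff$zero_lag)
  }
  trial
}
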