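# EMG median-frequency tracking: the spectral fatigue index. Median
# frequency is the frequency splitting the band-limited power spectrum into
# equal halves; it compresses toward lower frequencies as a muscle fatigues.

# Single-taper periodogram of a numeric vector: power per FFT bin up to
# Nyquist, with bin frequencies.
periodogram_power <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x)
  half <- seq_len(floor(n / 2) + 1)
  list(freq_hz = (half - 1) * fs / n, power = Mod(X[half])^2)
}

# Interpolated frequency at which the piecewise-linear cumulative power
# first reaches `level` (cumulative anchored at 0 just below the first bin).
cum_crossing <- function(freq, power, level) {
  cs <- cumsum(power)
  i <- which(cs >= level)[1]
  c_prev <- if (i == 1) 0 else cs[i - 1]
  f_prev <- if (i == 1) freq[1] - (freq[2] - freq[1]) else freq[i - 1]
  f_prev + (level - c_prev) / (cs[i] - c_prev) * (freq[i] - f_prev)
}

#' Median frequency of an EMG segment
#'
#' The signal is transformed with an FFT; the median frequency is where the
#' cumulative power within the analysis band reaches half of the band's
#' total power, located by linear interpolation between frequency bins. The
#' crossing is computed from both ends of the band and averaged, so a
#' spectrum with two equal lines at 80 and 120 Hz yields 100 Hz. Invariant
#' to amplitude scaling.
#'
#' @param x numeric vector or `sampled_trace` (a filtered EMG segment).
#' @param fs sampling rate in Hz (taken from the trace if one is given).
#' @param band_hz analysis band, Hz (power outside is ignored).
#' @return median frequency in Hz, or NA for an all-zero segment.
#' @export
median_frequency <- function(x, fs = NULL, band_hz = c(30, 400)) {
  if (inherits(x, "sampled_trace")) {
    fs <- x$sample_rate_hz
    x <- x$values
  }
  if (is.null(fs)) stop("fs is required for a plain numeric vector")
  pg <- periodogram_power(x, fs)
  keep <- pg$freq_hz >= band_hz[1] & pg$freq_hz <= band_hz[2]
  f <- pg$freq_hz[keep]
  p <- pg$power[keep]
  total <- sum(p)
  if (total <= 0 || length(f) < 2) return(NA_real_)
  f_lo <- cum_crossing(f, p, total / 2)
  f_hi_rev <- cum_crossing(rev(band_hz[1] + band_hz[2] - f), rev(p), total / 2)
  f_hi <- band_hz[1] + band_hz[2] - f_hi_rev
  (f_lo + f_hi) / 2
}

#' Median-frequency time series of an EMG channel
#'
#' One median frequency per non-overlapping analysis window (2 s by
#' default); a trace shorter than one window yields an empty series.
#'
#' @param channel a `sampled_trace` (a filtered EMG channel).
#' @param window_s analysis window length, seconds.
#' @param band_hz analysis band, Hz.
#' @param channel_name muscle label carried into the result.
#' @return data.frame of class `spectral_series` with columns `times_s`
#'   (window centers), `mdf_hz`, `channel`.
#' @export
mdf_time_series <- function(channel, window_s = 2, band_hz = c(30, 400),
                            channel_name = NA_character_) {
  stopifnot(inherits(channel, "sampled_trace"))
  fs <- channel$sample_rate_hz
  nwin <- round(window_s * fs)
  n_seg <- floor(length(channel$values) / nwin)
  if (n_seg == 0) {
    out <- data.frame(times_s = numeric(0), mdf_hz = numeric(0),
                      channel = character(0), stringsAsFactors = FALSE)
    class(out) <- c("spectral_series", "data.frame")
    return(out)
  }
  mdf <- vapply(seq_len(n_seg), function(i) {
    seg <- channel$values[seq((i - 1) * nwin + 1, i * nwin)]
    median_frequency(seg, fs, band_hz)
  }, numeric(1))
  out <- data.frame(
    times_s = channel$t0_s + (seq_len(n_seg) - 0.5) * window_s,
    mdf_hz = mdf, channel = channel_name, stringsAsFactors = FALSE)
  class(out) <- c("spectral_series", "data.frame")
  out
}

#' Median-frequency change between baseline and a fatigued hold
#'
#' Percent reduction from the first 10 s of the baseline hold (the first 5
#' two-second windows) to the final 10 s of the fatigued hold (its last 5
#' windows): `100 * (baseline - final) / baseline`.
#'
#' @param baseline_series,final_series `spectral_series` covering at least
#'   10 s (5 windows) each.
#' @param n_windows windows that make up 10 s.
#' @return percent change (positive = decline), or NA if either series is
#'   too short.
#' @export
mdf_fatigue_change <- function(baseline_series, final_series, n_windows = 5) {
  if (nrow(baseline_series) < n_windows || nrow(final_series) < n_windows) {
    return(NA_real_)
  }
  base <- mean(baseline_series$mdf_hz[seq_len(n_windows)])
  final <- mean(utils::tail(final_series$mdf_hz, n_windows))
  100 * (base - final) / base
}
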