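# Shared fixtures and independent oracles, built in code at test time.

# Closed-form unit step response of a second-order system with natural
# frequency wn and damping zeta, evaluated at times ts (response is 0 for
# ts < 0). Covers under-, critically and over-damped regimes.
analytic_step_response <- function(ts, wn, zeta) {
  y <- numeric(length(ts))
  pos <- ts >= 0
  t <- ts[pos]
  if (zeta < 1) {
    wd <- wn * sqrt(1 - zeta^2)
    y[pos] <- 1 - exp(-zeta * wn * t) *
      (cos(wd * t) + zeta / sqrt(1 - zeta^2) * sin(wd * t))
  } else if (zeta == 1) {
    y[pos] <- 1 - exp(-wn * t) * (1 + wn * t)
  } else {
    s <- sqrt(zeta^2 - 1)
    l1 <- wn * (-zeta + s)
    l2 <- wn * (-zeta - s)
    y[pos] <- 1 + (l2 * exp(l1 * t) - l1 * exp(l2 * t)) / (l1 - l2)
  }
  y
}

# Closed-form peak overshoot (%) of an underdamped second-order step response.
analytic_peak_overshoot_pct <- function(zeta) {
  100 * exp(-pi * zeta / sqrt(1 - zeta^2))
}

# Build a response_segment directly from a force vector on the STEP window
# layout (6 s, onset at 1 s) or PULSE layout (3 s, onset at 1.5 s).
make_segment <- function(force_values, fs = 1000, task = "STEP",
                         baseline = 1, step = 0.4,
                         on_duration = if (task == "STEP") 4 else 0.05) {
  onset <- if (task == "STEP") 1 else 1.5
  n <- length(force_values)
  t <- (seq_len(n) - 1) / fs
  upper_idx <- t >= onset & t < onset + on_duration
  target <- rep(baseline, n)
  target[upper_idx] <- baseline + step
  response_segment(force = sampled_trace(force_values, fs),
                   target = sampled_trace(target, fs),
                   onset_s = onset, on_duration_s = on_duration,
                   baseline_bw = baseline, step_size_bw = step,
                   step_index = 1, task = task,
                   meta = list(participant_id = "T", condition = "PreFatigue",
                               task = task, repetition = 1, order = 1))
}

# A clean noise-free synthetic step segment (optionally filtered), for
# metric tests.
clean_step_segment <- function(period = 0.732, damping = 0.835,
                               filtered = TRUE, config = default_config()) {
  p <- plant_params(natural_period_s = period, damping_ratio = damping,
                    noise_cv = 0, drift_per_s = 0)
  spec <- task_spec("STEP", n_reps = 1, total_duration_s = 10)
  target <- make_target_waveform(spec)
  force <- simulate_force_response(target, p, seed = 1)
  trial <- trial_record("T", "PreFatigue", "STEP", 1, 726, force, target,
                        onsets_s = attr(target, "onsets_s"),
                        expected_steps = 1)
  if (filtered) trial <- preprocess_trial(trial, config)
  segment_step_task(trial)[[1]]
}

# Brute-force threshold-search oracle: resample the segment's force densely
# (default 100 kHz) by linear interpolation and locate threshold crossings
# by plain grid search, independently of the package's interpolated
# crossing logic. Returns rise/fall (ms) and overshoot (%) using the same
# window conventions.
dense_step_oracle <- function(seg, config = default_config(), fs_dense = 1e5) {
  mx <- config$metrics
  t <- legforce::trace_times(seg$force)
  td <- seq(t[1], t[length(t)], by = 1 / fs_dense)
  v <- stats::approx(t, seg$force$values, xout = td)$y
  th <- function(frac) seg$baseline_bw + frac * seg$step_size_bw
  onset <- seg$onset_s
  in_win <- function(from, to) td >= from & td < to
  first_up <- function(thr, from, to) {
    i <- which(v >= thr & in_win(from, to))
    if (length(i) == 0) NA_real_ else {
      # first entry into the window already above threshold is not a crossing
      j <- i[c(TRUE, diff(i) > 1)]
      k <- j[j > 1 & v[pmax(j - 1, 1)] < thr]
      if (length(k) == 0) NA_real_ else td[k[1]]
    }
  }
  first_down <- function(thr, from, to) {
    i <- which(v < thr & in_win(from, to))
    if (length(i) == 0) return(NA_real_)
    j <- i[c(TRUE, diff(i) > 1)]
    k <- j[j > 1 & v[pmax(j - 1, 1)] >= thr]
    if (length(k) == 0) NA_real_ else td[k[1]]
  }
  r_lo <- first_up(th(mx$rise_frac_lo), onset + mx$rise_window_s[1],
                   onset + mx$rise_window_s[2])
  r_hi <- first_up(th(mx$rise_frac_hi), onset + mx$rise_window_s[1],
                   onset + mx$rise_window_s[2])
  rise_ms <- if (is.na(r_lo) || is.na(r_hi) || r_hi < r_lo) NA_real_ else
    1000 * (r_hi - r_lo)
  if (seg$task == "STEP") {
    f_from <- mx$fall_window_s[1]; f_to <- mx$fall_window_s[2]
  } else {
    f_from <- onset + seg$on_duration_s; f_to <- td[length(td)] + 1 / fs_dense
  }
  f_hi <- first_down(th(mx$rise_frac_hi), f_from, f_to)
  f_lo <- if (is.na(f_hi)) NA_real_ else
    first_down(th(mx$rise_frac_lo), f_hi, f_to)
  fall_ms <- if (is.na(f_hi) || is.na(f_lo)) NA_real_ else 1000 * (f_lo - f_hi)
  # clamp the peak search to sampled instants inside the window: between
  # samples the linear interpolant cannot exceed the sample values, but
  # across the window edge it would borrow an outside sample
  eps_s <- 0.25 / seg$force$sample_rate_hz
  samp_in <- t[t >= onset + mx$rise_window_s[1] - eps_s &
                 t < onset + mx$rise_window_s[2] - eps_s]
  wo <- td >= min(samp_in) - 1e-9 & td <= max(samp_in) + 1e-9
  over_pct <- 100 * (max(v[wo]) - (seg$baseline_bw + seg$step_size_bw)) /
    seg$step_size_bw
  list(rise_ms = rise_ms, fall_ms = fall_ms, over_pct = over_pct)
}

# Brute-force median frequency: cumulative sum over the raw periodogram
# bins within the band, no interpolation (resolution = one bin).
brute_mdf <- function(x, fs, band = c(30, 400)) {
  n <- length(x)
  P <- Mod(stats::fft(x)[seq_len(floor(n / 2) + 1)])^2
  f <- (seq_len(floor(n / 2) + 1) - 1) * fs / n
  keep <- f >= band[1] & f <= band[2]
  P <- P[keep]; f <- f[keep]
  cs <- cumsum(P)
  f[which(cs >= cs[length(cs)] / 2)[1]]
}

# Hand-computed one-way repeated-measures decomposition for a complete
# participant x condition matrix (explicit sums of squares).
hand_rm_anova <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  F_stat <- (ss_cond / df1) / (ss_err / df2)
  list(F = F_stat, df_num = df1, df_den = df2,
       p = stats::pf(F_stat, df1, df2, lower.tail = FALSE))
}

# Per-response metric rows with controllable values/exclusions, for the
# statistics layer.
fake_rows <- function(participants, conditions = CONDITIONS,
                      n_steps = 10, value_fun, excluded_fun = NULL) {
  rows <- expand.grid(participant_id = participants, condition = conditions,
                      repetition = 1L, step_index = seq_len(n_steps),
                      stringsAsFactors = FALSE)
  rows$task <- "STEP"
  rows$order <- 1L
  rows$rise_time_ms <- mapply(value_fun, rows$participant_id, rows$condition,
                              rows$step_index)
  rows$excluded <- if (is.null(excluded_fun)) FALSE else
    mapply(excluded_fun, rows$participant_id, rows$condition, rows$step_index)
  rows
}

# Truncate a STEP/PULSE trial to its first two steps so I/O tests stay small.
reduce_trial_for_test <- function(trial, n_steps = 2) {
  fs <- trial$force$sample_rate_hz
  keep <- trial$onsets_s[n_steps] + 7
  n <- round(keep * fs)
  trial$force <- sampled_trace(trial$force$values[seq_len(n)], fs)
  trial$target <- sampled_trace(trial$target$values[seq_len(n)], fs)
  trial$onsets_s <- trial$onsets_s[seq_len(n_steps)]
  trial$expected_steps <- n_steps
  trial
}

# Per-participant final MVC of the Pre-Fatigue and last fatigue conditions.
final_mvc_table <- function(task_rows) {
  mvc <- task_rows[task_rows$task == "MVC" & task_rows$ok, , drop = FALSE]
  last_of <- function(g) g$mean_force_bw[which.max(g$repetition)]
  pids <- sort(unique(mvc$participant_id))
  pre <- vapply(pids, function(p) {
    last_of(mvc[mvc$participant_id == p & mvc$condition == "PreFatigue", ])
  }, numeric(1))
  post <- vapply(pids, function(p) {
    last_of(mvc[mvc$participant_id == p & mvc$condition == "Fatigue3", ])
  }, numeric(1))
  data.frame(participant_id = pids, pre = pre, post = post)
}
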