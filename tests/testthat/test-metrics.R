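# Step-response characteristics, MVC means and hold-task variability.

test_that("rise time of a 0.5-s linear ramp is 400 ms", {
  fs <- 1000
  t <- (seq_len(6000) - 1) / fs
  v <- 1 + 0.4 * pmin(1, pmax(0, (t - 1) / 0.5))
  rt <- rise_time(make_segment(v))
  expect_true(rt$ok)
  expect_equal(rt$value_ms, 400, tolerance = 1e-6)
})

test_that("an instantaneous step has (near-)zero rise time", {
  # at 1 kHz both crossings interpolate inside one sample interval
  v <- c(rep(1, 1000), rep(1.4, 5000))
  rt <- rise_time(make_segment(v))
  expect_lt(rt$value_ms, 1)
  # densely sampled, the rise tends to zero
  v_hi <- c(rep(1, 100000), rep(1.4, 500000))
  rt_hi <- rise_time(make_segment(v_hi, fs = 1e5))
  expect_lt(rt_hi$value_ms, 0.01)
})

test_that("rise time is uncomputable when thresholds are never crossed", {
  rt <- rise_time(make_segment(rep(1, 6000)))
  expect_false(rt$ok)
  expect_true(is.na(rt$value_ms))
})

test_that("bandwidth is 0.35 over the rise time in seconds", {
  expect_equal(bandwidth(350), 1.0)
  expect_equal(bandwidth(500), 0.7)
  expect_equal(bandwidth(303), 1.155, tolerance = 1e-3)
  expect_true(is.na(bandwidth(NA_real_)))
  expect_true(is.na(bandwidth(0)))
  # exact identity for every computed pair
  for (ms in c(87.3, 150, 303, 512.7)) {
    expect_equal(bandwidth(ms) * (ms / 1000), 0.35, tolerance = 1e-14)
  }
})

test_that("fall time of a 1-s linear descent is 800 ms", {
  fs <- 1000
  t <- (seq_len(6000) - 1) / fs
  v <- 1 + 0.4 * pmin(1, pmax(0, (t - 1) / 0.2)) -
    0.4 * pmin(1, pmax(0, (t - 4.5) / 1.0))
  ft <- fall_time(make_segment(v))
  expect_true(ft$ok)
  expect_equal(ft$value_ms, 800, tolerance = 1e-6)
  # instantaneous drop
  v2 <- c(rep(1, 1000), rep(1.4, 4000), rep(1, 1000))
  expect_lt(fall_time(make_segment(v2))$value_ms, 1)
})

test_that("overshoot is the signed peak excess as a percent of the step", {
  fs <- 1000
  t <- (seq_len(6000) - 1) / fs
  base <- 1 + 0.4 * pmin(1, pmax(0, (t - 1) / 0.2)) -
    0.4 * pmin(1, pmax(0, (t - 5) / 0.2))
  peak <- base + 0.04 * exp(-((t - 1.6) / 0.1)^2)  # peak at 1.44 BW
  ov <- overshoot(make_segment(peak))
  expect_equal(ov$value_pct, 10, tolerance = 0.1)
  expect_equal(overshoot(make_segment(base))$value_pct, 0, tolerance = 1e-6)
  # a response that never reaches the target has negative overshoot
  low <- 1 + 0.36 * pmin(1, pmax(0, (t - 1) / 0.2))
  expect_lt(overshoot(make_segment(low))$value_pct, 0)
})

test_that("steady-state error and variability follow their definitions", {
  fs <- 1000
  t <- (seq_len(6000) - 1) / fs
  on <- t >= 1 & t < 5
  v <- rep(1, 6000); v[on] <- 1.386
  expect_equal(steady_state_error(make_segment(v))$value_pct, 1,
               tolerance = 1e-9)
  v[on] <- 1.4
  expect_equal(steady_state_error(make_segment(v))$value_pct, 0)
  expect_equal(steady_state_variability(make_segment(v))$value_pct, 0)
  v[on] <- 1.54
  expect_equal(steady_state_error(make_segment(v))$value_pct, 10,
               tolerance = 1e-9)
  # CV definition: SD/mean over the settled window
  set.seed(11)
  v[on] <- 1.4 * (1 + 0.01 * rnorm(sum(on)))
  sv <- steady_state_variability(make_segment(v))$value_pct
  expect_equal(sv, 100 * sd(v[t >= 3 & t < 5]) / mean(v[t >= 3 & t < 5]))
})

test_that("the CV estimator recovers injected signal-dependent noise", {
  # 2% multiplicative noise measured across 50 seeded segments
  fs <- 1000
  t <- (seq_len(6000) - 1) / fs
  on <- t >= 1 & t < 5
  est <- vapply(1:50, function(s) {
    set.seed(s)
    v <- rep(1, 6000)
    v[on] <- 1.4 * (1 + 0.02 * rnorm(sum(on)))
    steady_state_variability(make_segment(v))$value_pct
  }, numeric(1))
  expect_equal(mean(est), 2, tolerance = 0.05)
})

test_that("MVC mean follows its 4-8 s window definition", {
  fs <- 1000
  flat <- trial_record("T", "PreFatigue", "MVC", 1, 726,
                       sampled_trace(rep(2.95, 10 * fs), fs),
                       sampled_trace(rep(5, 10 * fs), fs))
  expect_equal(mvc_mean(flat)$mean_force_bw, 2.95)
  t <- (seq_len(10 * fs) - 1) / fs
  ramp <- trial_record("T", "PreFatigue", "MVC", 1, 726,
                       sampled_trace(0.3 * t, fs),
                       sampled_trace(rep(5, 10 * fs), fs))
  expect_equal(mvc_mean(ramp)$mean_force_bw, 1.8, tolerance = 1e-3)
  short <- trial_record("T", "PreFatigue", "MVC", 1, 726,
                        sampled_trace(rep(2, 5 * fs), fs),
                        sampled_trace(rep(5, 5 * fs), fs))
  expect_false(mvc_mean(short)$ok)
})

test_that("hold variability yields one CV per second after the first 5 s", {
  fs <- 1000
  hold <- function(values) {
    trial_record("T", "Fatigue1", "HOLD", 1, 726,
                 sampled_trace(values, fs),
                 sampled_trace(rep(1.74, length(values)), fs))
  }
  hv <- hold_variability(hold(rep(1.74, 73 * fs)))
  expect_length(hv$cv_per_second, 68)
  expect_true(all(hv$cv_per_second == 0))
  expect_equal(hv$final10_mean_cv_pct, 0)
  # injected multiplicative noise is recovered in the final-10-s summary
  set.seed(21)
  noisy <- 1.74 * (1 + 0.0061 * rnorm(73 * fs))
  hv <- hold_variability(hold(noisy))
  expect_equal(hv$final10_mean_cv_pct, 0.61, tolerance = 0.08)
  expect_false(hold_variability(hold(rep(1.74, 12 * fs)))$ok)
})

test_that("metrics are invariant to the segment's time origin", {
  seg <- clean_step_segment()
  a <- step_metrics(seg)
  shifted <- seg
  shifted$force$t0_s <- shifted$force$t0_s + 7
  shifted$target$t0_s <- shifted$target$t0_s + 7
  shifted$onset_s <- shifted$onset_s + 7
  b <- step_metrics(shifted)
  for (col in c("rise_time_ms", "bandwidth_hz", "fall_time_ms",
                "overshoot_pct", "steady_state_error_pct",
                "steady_state_variability_pct")) {
    expect_equal(a[[col]], b[[col]], info = col)
  }
})

test_that("metrics are robust to dense resampling of the segment", {
  seg <- clean_step_segment()
  a <- step_metrics(seg)
  # linearly resample force and target to 10 kHz
  t <- trace_times(seg$force)
  td <- seq(t[1], t[length(t)], by = 1e-4)
  dense <- seg
  dense$force <- sampled_trace(stats::approx(t, seg$force$values, td)$y, 1e4)
  dense$target <- sampled_trace(stats::approx(t, seg$target$values, td)$y, 1e4)
  b <- step_metrics(dense)
  expect_lt(abs(a$rise_time_ms - b$rise_time_ms), 1)
  expect_lt(abs(a$fall_time_ms - b$fall_time_ms), 1)
  expect_lt(abs(a$overshoot_pct - b$overshoot_pct), 0.1)
})

test_that("slowing the plant strictly increases measured rise time", {
  rises <- vapply(c(0.55, 0.732, 0.95, 1.2), function(per) {
    rise_time(clean_step_segment(period = per))$value_ms
  }, numeric(1))
  expect_true(all(diff(rises) > 0))
})
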