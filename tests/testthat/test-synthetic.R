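# Target waveforms, the second-order plant, EMG emulation and the session
# protocol.

test_that("step target waveform has exact timing and geometry", {
  target <- make_target_waveform(task_spec("STEP"))
  expect_length(target$values, 73000)
  expect_equal(sort(unique(target$values)), c(1.0, 1.4))
  expect_equal(sum(target$values == 1.4), 10 * 4000)
  onsets <- attr(target, "onsets_s")
  expect_equal(onsets, 3 + (0:9) * 7)
  # each high interval is a contiguous run of exactly 4000 samples
  r <- rle(target$values)
  expect_equal(sum(r$values == 1.4), 10)
  expect_true(all(r$lengths[r$values == 1.4] == 4000))
})

test_that("pulse target high intervals are exactly 0.05 s", {
  target <- make_target_waveform(task_spec("PULSE"))
  r <- rle(target$values)
  expect_equal(sum(r$values == 1.4), 10)
  expect_true(all(r$lengths[r$values == 1.4] == 50))
  expect_length(target$values, 73000)
})

test_that("degenerate and invalid task specs are handled", {
  flat <- make_target_waveform(task_spec("STEP", n_reps = 0))
  expect_true(all(flat$values == 1.0))
  expect_error(task_spec("STEP", n_reps = 11), "exceeds total_duration_s")
  expect_error(task_spec("STEP", baseline_bw = -1), "baseline_bw")
  expect_error(task_spec("STEP", sample_rate_hz = 0), "sample_rate_hz")
  expect_error(task_spec("HOLD", hold_level_bw = 0.5), "hold_level_bw")
})

test_that("target waveforms are idempotent under regeneration", {
  a <- make_target_waveform(task_spec("STEP"))
  b <- make_target_waveform(task_spec("STEP"))
  expect_identical(a$values, b$values)
  expect_identical(attr(a, "onsets_s"), attr(b, "onsets_s"))
})

test_that("noise-free responses match the closed-form step response", {
  fs <- 1000
  spec <- task_spec("STEP", n_reps = 1, total_duration_s = 10)
  target <- make_target_waveform(spec)
  onset <- attr(target, "onsets_s")[1]
  for (zeta in c(0.5, 0.835, 1.0, 1.5)) {
    p <- plant_params(damping_ratio = zeta, noise_cv = 0, drift_per_s = 0)
    y <- simulate_force_response(target, p, seed = 1)
    t <- trace_times(y)
    wn <- 2 * pi / p$natural_period_s
    # the step lasts 4 s; compare along the rising plateau portion only
    keep <- t < onset + 4
    ts <- t[keep] - onset - p$motor_delay_s
    ya <- 1 + 0.4 * analytic_step_response(ts, wn, zeta)
    expect_lt(sqrt(mean((y$values[keep] - ya)^2)), 1e-6)
  }
})

test_that("overdamped noise-free responses never overshoot", {
  spec <- task_spec("STEP", n_reps = 1, total_duration_s = 10)
  target <- make_target_waveform(spec)
  p <- plant_params(damping_ratio = 1.2, noise_cv = 0, drift_per_s = 0)
  y <- simulate_force_response(target, p, seed = 1)
  expect_lte(max(y$values), 1.4 + 1e-12)
  # monotone rise over the step-on interval
  t <- trace_times(y)
  rising <- t >= 3 & t < 7
  expect_true(all(diff(y$values[rising]) >= -1e-12))
})

test_that("underdamped peak overshoot matches the closed form within 0.1%", {
  spec <- task_spec("STEP", n_reps = 1, total_duration_s = 10)
  target <- make_target_waveform(spec)
  p <- plant_params(damping_ratio = 0.5, noise_cv = 0, drift_per_s = 0)
  y <- simulate_force_response(target, p, seed = 1)
  trial <- trial_record("T", "PreFatigue", "STEP", 1, 726, y, target,
                        onsets_s = attr(target, "onsets_s"),
                        expected_steps = 1)
  seg <- segment_step_task(trial)[[1]]
  ov <- overshoot(seg)$value_pct
  expect_lt(abs(ov - analytic_peak_overshoot_pct(0.5)), 0.1)
})

test_that("an unattainable MVC target saturates at the plant maximum", {
  target <- make_target_waveform(task_spec("MVC"))
  p <- plant_params(mvc_bw = 2.2, noise_cv = 0, drift_per_s = 0)
  y <- simulate_force_response(target, p, seed = 1)
  trial <- trial_record("T", "PreFatigue", "MVC", 1, 726, y, target)
  expect_equal(mvc_mean(trial)$mean_force_bw, 2.2, tolerance = 1e-10)
})

test_that("simulation is bit-identical under a fixed seed", {
  target <- make_target_waveform(task_spec("STEP", n_reps = 2,
                                           total_duration_s = 17))
  p <- plant_params()
  a <- simulate_force_response(target, p, seed = 7)
  b <- simulate_force_response(target, p, seed = 7)
  c <- simulate_force_response(target, p, seed = 8)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
})

test_that("synthetic EMG is band-centered, shiftable and force-gated", {
  fs <- 1000
  force <- sampled_trace(rep(1.5, 10 * fs), fs)
  params <- emg_params(band_low_hz = c(gastroc_lateralis = 60),
                       band_high_hz = c(gastroc_lateralis = 140))
  emg <- simulate_emg(force, params, mdf_shift = 1, seed = 3)
  ch <- emg$channels$gastroc_lateralis
  mdfs <- mdf_time_series(ch)$mdf_hz
  expect_lt(abs(mean(mdfs) - 100), 4)
  emg9 <- simulate_emg(force, params, mdf_shift = 0.9, seed = 3)
  mdfs9 <- mdf_time_series(emg9$channels$gastroc_lateralis)$mdf_hz
  expect_lt(abs(mean(mdfs9) - 90), 4)
  # zero force gives all-zero channels
  z <- simulate_emg(sampled_trace(rep(0, 4000), fs), params, 1, seed = 1)
  expect_true(all(z$channels$gastroc_lateralis$values == 0))
  # shifted band beyond Nyquist is rejected
  big <- emg_params(band_low_hz = c(m = 400), band_high_hz = c(m = 900))
  expect_error(simulate_emg(force, big, mdf_shift = 1.2), "Nyquist")
})

test_that("the session protocol matches the study design", {
  trials <- simulate_session(plant_params(), fatigue_profile(), seed = 1,
                             tasks = character(0))
  expect_length(trials, 0)
  trials <- simulate_session(plant_params(), fatigue_profile(), seed = 1)
  proto <- data.frame(
    condition = vapply(trials, function(tr) tr$condition, character(1)),
    task = vapply(trials, function(tr) tr$task, character(1)))
  pre <- proto$task[proto$condition == "PreFatigue"]
  expect_equal(sum(pre == "MVC"), 2)
  expect_equal(sum(pre == "STEP"), 3)
  expect_equal(sum(pre == "PULSE"), 2)
  expect_equal(sum(pre == "HOLD"), 1)  # practice hold (baseline variability)
  for (cond in c("Fatigue1", "Fatigue2", "Fatigue3")) {
    fat <- proto$task[proto$condition == cond]
    expect_equal(sum(fat == "HOLD"), 3)
    expect_equal(sum(fat == "MVC"), 3)
    expect_equal(sum(fat == "STEP"), 3)
  }
  expect_equal(sum(proto$task == "PULSE" & proto$condition == "Fatigue3"), 2)
  expect_equal(proto$task[proto$condition == "Training"],
               c("MVC", "MVC", "STEP", "STEP", "STEP"))
  # per-trial determinism: regenerating the session reproduces every trace
  again <- simulate_session(plant_params(), fatigue_profile(), seed = 1)
  expect_identical(trials[[10]]$force$values, again[[10]]$force$values)
})

test_that("fatigue profile validation rejects bad multipliers", {
  expect_error(fatigue_profile(mvc_scale = c(1, 1, 1, 1, 0)), "mvc_scale")
  expect_error(fatigue_profile(rise_scale = c(1, 1, 1)), "rise_scale")
})
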