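# Orchestration: generate -> preprocess -> segment -> measure -> summarize
# -> test, with per-trial fault isolation and a run manifest.

#' Analyze one trial
#'
#' Filters the force per configuration, then dispatches on task: Step/Pulse
#' trials are segmented and measured per response (with exclusion flags);
#' MVC trials yield the 4-8 s mean force; Hold trials yield per-second CVs
#' and the final-10-s summary, plus per-channel median-frequency series when
#' EMG is attached (EMG is band-pass/band-stop filtered and delay-corrected
#' first).
#'
#' @param trial a `trial_record`.
#' @param config configuration list.
#' @return list with `response_rows` (Step/Pulse; NULL otherwise),
#'   `task_row` (MVC/Hold one-row summary; NULL otherwise), `mdf` (list of
#'   `spectral_series` by muscle; NULL without EMG).
#' @export
analyze_trial <- function(trial, config = default_config()) {
  trial_f <- preprocess_trial(trial, config)
  response_rows <- NULL
  task_row <- NULL
  mdf <- NULL
  if (trial$task %in% c("STEP", "PULSE")) {
    segs <- if (trial$task == "STEP") segment_step_task(trial_f) else
      segment_pulse_task(trial_f)
    response_rows <- do.call(rbind, lapply(segs, step_metrics, config = config))
  } else if (trial$task == "MVC") {
    mv <- mvc_mean(trial_f, config)
    task_row <- data.frame(participant_id = trial$participant_id,
                           condition = trial$condition, task = "MVC",
                           repetition = trial$repetition, order = trial$order,
                           mean_force_bw = mv$mean_force_bw,
                           final10_mean_cv_pct = NA_real_,
                           ok = mv$ok, stringsAsFactors = FALSE)
  } else if (trial$task == "HOLD") {
    hv <- hold_variability(trial_f, config)
    task_row <- data.frame(participant_id = trial$participant_id,
                           condition = trial$condition, task = "HOLD",
                           repetition = trial$repetition, order = trial$order,
                           mean_force_bw = NA_real_,
                           final10_mean_cv_pct = hv$final10_mean_cv_pct,
                           ok = hv$ok, stringsAsFactors = FALSE)
    if (!is.null(trial$emg)) {
      ef <- config$emg_filter
      emg <- filter_emg(trial$emg, ef$band_hz, ef$notch_hz, ef$order)
      emg <- correct_sensor_delay(emg, ef$sensor_delay_s)
      mdf <- lapply(names(emg$channels), function(nm) {
        mdf_time_series(emg$channels[[nm]], config$emg$window_s,
                        config$emg$band_hz, channel_name = nm)
      })
      names(mdf) <- names(emg$channels)
    }
  }
  list(response_rows = response_rows, task_row = task_row, mdf = mdf)
}

#' Analyze a list of trials
#'
#' Runs [analyze_trial()] over a session (or any trial collection),
#' isolating per-trial failures: a trial that errors is recorded in the
#' manifest and the run continues.
#'
#' @param trials list of `trial_record`.
#' @param config configuration list.
#' @return list with `response_rows`, `task_rows`, `mdf` (nested list keyed
#'   `participant|condition|HOLD|rep`), and `manifest` (per-trial status
#'   data.frame).
#' @export
analyze_trials <- function(trials, config = default_config()) {
  response_rows <- list()
  task_rows <- list()
  mdf <- list()
  status <- character(length(trials))
  message_log <- character(length(trials))
  for (i in seq_along(trials)) {
    trial <- trials[[i]]
    res <- tryCatch(analyze_trial(trial, config), error = function(e) e)
    if (inherits(res, "error")) {
      status[i] <- "failed"
      message_log[i] <- conditionMessage(res)
      next
    }
    status[i] <- "processed"
    message_log[i] <- ""
    if (!is.null(res$response_rows)) {
      response_rows[[length(response_rows) + 1]] <- res$response_rows
    }
    if (!is.null(res$task_row)) {
      task_rows[[length(task_rows) + 1]] <- res$task_row
    }
    if (!is.null(res$mdf)) {
      key <- paste(trial$participant_id, trial$condition, trial$task,
                   trial$repetition, sep = "|")
      mdf[[key]] <- res$mdf
    }
  }
  ids <- vapply(trials, function(tr) {
    paste(tr$participant_id, tr$condition, tr$task, tr$repetition, sep = "|")
  }, character(1))
  manifest <- data.frame(trial = ids, status = status,
                         message = message_log, stringsAsFactors = FALSE)
  resp <- if (length(response_rows)) do.call(rbind, response_rows) else NULL
  tasks <- if (length(task_rows)) do.call(rbind, task_rows) else NULL
  list(response_rows = resp, task_rows = tasks, mdf = mdf,
       manifest = manifest)
}

#' Simulate and analyze a whole synthetic study
#'
#' Generates `n_participants` sessions with between-participant plant
#' variation (see [draw_participant_plants()]) and analyzes each with the
#' full pipeline, keeping only the metric tables (traces are discarded as
#' it goes, so memory stays flat).
#'
#' @param n_participants number of simulated participants.
#' @param seed master integer seed.
#' @param config configuration list.
#' @param base_plant average-participant plant.
#' @param profile fatigue profile.
#' @param emg simulate and analyze Hold-trial EMG.
#' @param tasks optional task subset passed to [simulate_session()].
#' @param vary_participants draw between-participant plant variation
#'   (`FALSE` gives identical plants).
#' @return list with `response_rows`, `task_rows`, `mdf`, `manifest`.
#' @export
run_synthetic_study <- function(n_participants = 18, seed = 1,
                                config = default_config(),
                                base_plant = plant_params(),
                                profile = fatigue_profile(), emg = FALSE,
                                tasks = NULL, vary_participants = TRUE) {
  plants <- if (vary_participants) {
    draw_participant_plants(n_participants, seed, base_plant)
  } else {
    rep(list(base_plant), n_participants)
  }
  out <- list(response_rows = list(), task_rows = list(), mdf = list(),
              manifest = list())
  for (i in seq_len(n_participants)) {
    pid <- sprintf("P%02d", i)
    trials <- simulate_session(plants[[i]], profile,
                               seed = derive_seed(seed, "session", i),
                               participant_id = pid, emg = emg, tasks = tasks)
    res <- analyze_trials(trials, config)
    out$response_rows[[i]] <- res$response_rows
    out$task_rows[[i]] <- res$task_rows
    out$mdf <- c(out$mdf, res$mdf)
    out$manifest[[i]] <- res$manifest
  }
  list(response_rows = do.call(rbind, out$response_rows),
       task_rows = do.call(rbind, out$task_rows),
       mdf = out$mdf,
       manifest = do.call(rbind, out$manifest))
}

# Final MVC per condition: the mean force of the last MVC repetition.
final_mvc_by_condition <- function(task_rows) {
  mvc <- task_rows[task_rows$task == "MVC" & task_rows$ok, , drop = FALSE]
  key <- interaction(mvc$participant_id, mvc$condition, drop = TRUE)
  pieces <- lapply(split(mvc, key), function(g) {
    g[which.max(g$repetition), c("participant_id", "condition",
                                 "mean_force_bw")]
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Session-level fatigue effect estimates from pipeline tables
#'
#' Computes, per participant, the pipeline's estimates of the programmed
#' fatigue effects and averages them: percent MVC decline (final Pre-Fatigue
#' MVC vs final last-fatigue MVC), the rise-time ratio (last-fatigue /
#' Pre-Fatigue condition means over the first five usable responses), the
#' hold-CV ratio (mean of the last fatigue condition's final-10-s CVs vs the
#' Pre-Fatigue practice hold), and the percent median-frequency decline
#' (baseline = first 10 s of the first fatiguing hold, final = last 10 s of
#' the last one) when EMG was analyzed.
#'
#' @param study output of [run_synthetic_study()] (or the same tables from
#'   [analyze_trials()]).
#' @param mdf_channel muscle used for the median-frequency effect.
#' @return named list of effect estimates (means over participants).
#' @export
study_effects <- function(study, mdf_channel = "gastroc_lateralis") {
  task_rows <- study$task_rows
  effects <- list(mvc_decline_pct = NA_real_, rise_ratio = NA_real_,
                  hold_cv_ratio = NA_real_, mdf_decline_pct = NA_real_)
  # MVC decline
  fm <- final_mvc_by_condition(task_rows)
  wide <- stats::reshape(fm, idvar = "participant_id", timevar = "condition",
                         direction = "wide")
  pre <- wide[["mean_force_bw.PreFatigue"]]
  post <- wide[["mean_force_bw.Fatigue3"]]
  keep <- !is.na(pre) & !is.na(post)
  if (any(keep)) {
    effects$mvc_decline_pct <- mean(100 * (pre[keep] - post[keep]) / pre[keep])
  }
  # rise-time ratio
  if (!is.null(study$response_rows)) {
    s <- summarize_conditions(study$response_rows, "rise_time_ms")
    sw <- summary_wide(s, c("PreFatigue", "Fatigue3"))
    if (nrow(sw$matrix) > 0) {
      effects$rise_ratio <- mean(sw$matrix[, "Fatigue3"] /
                                   sw$matrix[, "PreFatigue"])
    }
  }
  # hold CV ratio
  hold <- task_rows[task_rows$task == "HOLD" & task_rows$ok, , drop = FALSE]
  if (nrow(hold) > 0) {
    key <- split(hold, hold$participant_id)
    ratios <- vapply(key, function(g) {
      base <- g$final10_mean_cv_pct[g$condition == "PreFatigue"]
      fin <- g$final10_mean_cv_pct[g$condition == "Fatigue3"]
      if (length(base) == 0 || length(fin) == 0) return(NA_real_)
      mean(fin) / mean(base)
    }, numeric(1))
    if (any(!is.na(ratios))) effects$hold_cv_ratio <- mean(ratios,
                                                           na.rm = TRUE)
  }
  # MDF decline
  if (length(study$mdf) > 0) {
    keys <- names(study$mdf)
    parts <- unique(sub("\\|.*", "", keys))
    drops <- vapply(parts, function(p) {
      bkey <- keys[startsWith(keys, paste0(p, "|Fatigue1|HOLD|1"))]
      fkeys <- keys[startsWith(keys, paste0(p, "|Fatigue3|HOLD|"))]
      if (length(bkey) == 0 || length(fkeys) == 0) return(NA_real_)
      freps <- as.integer(sub(".*\\|", "", fkeys))
      fkey <- fkeys[which.max(freps)]
      mdf_fatigue_change(study$mdf[[bkey]][[mdf_channel]],
                         study$mdf[[fkey]][[mdf_channel]])
    }, numeric(1))
    if (any(!is.na(drops))) effects$mdf_decline_pct <- mean(drops,
                                                            na.rm = TRUE)
  }
  effects
}

#' Run the pipeline over a directory of trial files
#'
#' Reads every trial (`*.json` sidecars found under `input_dir`), analyzes
#' each with per-trial fault isolation, writes the response metrics table,
#' the MVC/Hold task table, the condition summaries, ANOVA and pairwise
#' tables for each step-response characteristic, and a JSON run manifest.
#' Deterministic: identical inputs and configuration give byte-identical
#' tables.
#'
#' @param input_dir directory of trials written by [write_trial()].
#' @param output_dir destination directory (created if needed).
#' @param config configuration list.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(input_dir, output_dir,
                         config = default_config()) {
  metas <- sort(list.files(input_dir, pattern = "\\.json$",
                           full.names = TRUE))
  metas <- metas[!grepl("manifest", basename(metas))]
  if (length(metas) == 0) stop(sprintf("no trials found in %s", input_dir))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  trials <- list()
  read_status <- character(0)
  for (mp in metas) {
    base <- sub("\\.json$", "", mp)
    tr <- tryCatch(read_trial(base), error = function(e) e)
    if (inherits(tr, "error")) {
      read_status <- c(read_status, stats::setNames(conditionMessage(tr),
                                                    basename(base)))
    } else {
      trials[[length(trials) + 1]] <- tr
    }
  }
  res <- analyze_trials(trials, config)
  write_metrics_table(res$response_rows,
                      file.path(output_dir, "response_metrics.csv"))
  if (!is.null(res$task_rows)) {
    utils::write.csv(res$task_rows, file.path(output_dir, "task_metrics.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  metric_cols <- c("rise_time_ms", "bandwidth_hz", "fall_time_ms",
                   "overshoot_pct", "steady_state_error_pct",
                   "steady_state_variability_pct")
  anova_rows <- list()
  pairwise_rows <- list()
  if (!is.null(res$response_rows)) {
    n_complete <- function(s) nrow(summary_wide(s)$matrix)
    for (mc in metric_cols) {
      s <- summarize_conditions(res$response_rows, mc)
      if (nrow(s) == 0 || n_complete(s) < 2) next
      a <- rm_anova(s, mc)
      anova_rows[[mc]] <- data.frame(metric = mc, F = a$F,
                                     df_num = a$df_num, df_den = a$df_den,
                                     p = a$p, n = a$n,
                                     stringsAsFactors = FALSE)
      if (!is.na(a$p) && a$p < config$stats$alpha) {
        pairwise_rows[[mc]] <- bonferroni_pairwise(s, mc)
      }
    }
  }
  if (length(anova_rows) > 0) {
    utils::write.csv(do.call(rbind, anova_rows),
                     file.path(output_dir, "anova.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  if (length(pairwise_rows) > 0) {
    utils::write.csv(do.call(rbind, pairwise_rows),
                     file.path(output_dir, "pairwise.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  n_failed_reads <- length(read_status)
  excl_tally <- if (!is.null(res$response_rows)) {
    sum(res$response_rows$excluded)
  } else 0L
  manifest <- list(
    n_inputs = length(metas),
    n_read = length(trials),
    n_failed_reads = n_failed_reads,
    failed_reads = as.list(read_status),
    n_processed = sum(res$manifest$status == "processed"),
    n_failed = sum(res$manifest$status == "failed"),
    exclusions = excl_tally,
    trials = res$manifest,
    outputs = list.files(output_dir))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(manifest)
}

# An adversarial STEP/PULSE trial whose force violates exactly one
# exclusion criterion on its single step.
adversarial_trial <- function(reason, participant_id = "ADV",
                              body_weight_n = 726) {
  fs <- 1000
  task <- if (reason %in% c("pulse_early_rise", "late_fall")) "PULSE" else
    "STEP"
  if (task == "STEP") {
    spec <- task_spec("STEP", n_reps = 1, total_duration_s = 10,
                      off_duration_s = 3)
    target <- make_target_waveform(spec)
    onset <- attr(target, "onsets_s")[1]
    t <- trace_times(target)
    ramp <- function(t0, dur = 0.2) pmin(1, pmax(0, (t - t0) / dur))
    v <- switch(reason,
      # a brief early push (back at baseline before the pre-onset window)
      # followed by a normal response: only criterion 1 fires
      early_rise = 1 + 0.4 * (ramp(onset - 0.65, 0.03) -
                                ramp(onset - 0.6, 0.03)) +
        0.4 * ramp(onset) - 0.4 * ramp(onset + spec$on_duration_s),
      no_rise = rep(1, length(t)),
      elevated_baseline = 1 + 0.08 +
        0.32 * ramp(onset) - 0.4 * ramp(onset + spec$on_duration_s),
      early_fall = 1 + 0.4 * ramp(onset) -
        0.4 * ramp(onset + spec$on_duration_s - 1.5),
      stop("unknown step reason"))
  } else {
    spec <- task_spec("PULSE", n_reps = 1, total_duration_s = 10,
                      off_duration_s = 6.95)
    target <- make_target_waveform(spec)
    onset <- attr(target, "onsets_s")[1]
    t <- trace_times(target)
    ramp <- function(t0, dur = 0.1) pmin(1, pmax(0, (t - t0) / dur))
    v <- switch(reason,
      pulse_early_rise = 1 + 0.4 * ramp(onset - 0.4) -
        0.4 * ramp(onset + 0.3),
      late_fall = 1 + 0.4 * ramp(onset) - 0.4 * ramp(onset + 0.8),
      stop("unknown pulse reason"))
  }
  trial_record(participant_id, "PreFatigue", task, 1, body_weight_n,
               sampled_trace(v, fs), target,
               onsets_s = attr(target, "onsets_s"), expected_steps = 1)
}

#' Write a synthetic fixture set to disk
#'
#' Writes a miniature synthetic study (by default 18 participants with
#' reduced task durations: 3 steps/pulses per trial and 24-s holds) plus six
#' adversarial single-step trials, one per exclusion criterion, each
#' violating exactly that criterion. Regeneration with the same seed
#' produces identical files.
#'
#' @param out_dir destination directory.
#' @param seed master integer seed.
#' @param n_participants number of participants.
#' @param reduced use reduced task durations (full 73-s protocol if FALSE).
#' @return invisibly, the list of files written.
#' @export
generate_fixtures <- function(out_dir, seed = 1, n_participants = 18,
                              reduced = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  plants <- draw_participant_plants(n_participants, seed)
  for (i in seq_len(n_participants)) {
    pid <- sprintf("P%02d", i)
    trials <- simulate_session(plants[[i]], fatigue_profile(),
                               seed = derive_seed(seed, "session", i),
                               participant_id = pid)
    if (reduced) {
      trials <- Filter(function(tr) tr$repetition == 1, trials)
      trials <- lapply(trials, reduce_trial)
    }
    for (tr in trials) {
      write_trial(tr, file.path(out_dir, sprintf("%s_%s_%s_%d", pid,
                                                 tr$condition, tr$task,
                                                 tr$repetition)))
    }
  }
  reasons <- c("early_rise", "no_rise", "elevated_baseline", "early_fall",
               "pulse_early_rise", "late_fall")
  for (r in reasons) {
    write_trial(adversarial_trial(r),
                file.path(out_dir, sprintf("ADV_%s", r)))
  }
  invisible(list.files(out_dir, full.names = TRUE))
}

# Truncate a trial to its first 3 steps (STEP/PULSE) or 24 s (HOLD/MVC).
reduce_trial <- function(trial) {
  if (trial$task %in% c("STEP", "PULSE")) {
    keep_s <- if (trial$task == "STEP") 3 + 3 * 7 + 3 else 3 + 3 * 7 + 3
    onsets <- trial$onsets_s[seq_len(min(3, length(trial$onsets_s)))]
    n <- round(keep_s * trial$force$sample_rate_hz)
    n <- min(n, length(trial$force$values))
    trial$force <- sampled_trace(trial$force$values[seq_len(n)],
                                 trial$force$sample_rate_hz)
    trial$target <- sampled_trace(trial$target$values[seq_len(n)],
                                  trial$target$sample_rate_hz)
    trial$onsets_s <- onsets
    trial$expected_steps <- length(onsets)
  } else {
    keep_s <- if (trial$task == "MVC") 10 else 24
    n <- min(round(keep_s * trial$force$sample_rate_hz),
             length(trial$force$values))
    trial$force <- sampled_trace(trial$force$values[seq_len(n)],
                                 trial$force$sample_rate_hz)
    trial$target <- sampled_trace(trial$target$values[seq_len(n)],
                                  trial$target$sample_rate_hz)
  }
  trial
}
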