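# Condition-level statistics: participant x condition summaries from the
# first five usable step responses, one-way repeated-measures ANOVA across
# the five conditions, Bonferroni-corrected paired comparisons, and
# pooled-SD Cohen's d.

#' Participant x condition summary of a step-response metric
#'
#' For each participant and condition, the mean of the metric over the first
#' five non-excluded step responses in trial order (the responses
#' immediately following the condition's final MVC). Rows with fewer than
#' five usable responses use all available and are flagged; participants
#' with none get no row.
#'
#' @param rows per-response metric rows (see [step_metrics()]); only
#'   `task == "STEP"` rows are used unless `task` says otherwise.
#' @param metric metric column name, e.g. `"rise_time_ms"`.
#' @param n_first how many responses enter the mean.
#' @param task which task's responses to summarize.
#' @return data.frame with `participant_id`, `condition`, `metric`, `value`,
#'   `n_used`, `flagged`.
#' @export
summarize_conditions <- function(rows, metric, n_first = 5, task = "STEP") {
  stopifnot(metric %in% names(rows))
  rows <- rows[rows$task == task & !rows$excluded & !is.na(rows[[metric]]), ,
               drop = FALSE]
  rows <- rows[order(rows$participant_id, rows$condition, rows$repetition,
                     rows$step_index), , drop = FALSE]
  if (nrow(rows) == 0) {
    return(data.frame(participant_id = character(0), condition = character(0),
                      metric = character(0), value = numeric(0),
                      n_used = integer(0), flagged = logical(0),
                      stringsAsFactors = FALSE))
  }
  key <- interaction(rows$participant_id, rows$condition, drop = TRUE)
  pieces <- lapply(split(rows, key), function(g) {
    take <- utils::head(g, n_first)
    data.frame(participant_id = g$participant_id[1],
               condition = g$condition[1], metric = metric,
               value = mean(take[[metric]]), n_used = nrow(take),
               flagged = nrow(take) < n_first, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$participant_id,
            match(out$condition, CONDITIONS)), , drop = FALSE]
}

# participant x condition wide matrix of summary values, complete cases only
summary_wide <- function(summary_df, conditions = CONDITIONS) {
  conditions <- intersect(conditions, unique(summary_df$condition))
  wide <- stats::reshape(
    summary_df[, c("participant_id", "condition", "value")],
    idvar = "participant_id", timevar = "condition", direction = "wide")
  cols <- paste0("value.", conditions)
  missing_cols <- setdiff(cols, names(wide))
  for (mc in missing_cols) wide[[mc]] <- NA_real_
  m <- as.matrix(wide[, cols, drop = FALSE])
  rownames(m) <- wide$participant_id
  colnames(m) <- conditions
  complete <- stats::complete.cases(m)
  dropped <- rownames(m)[!complete]
  list(matrix = m[complete, , drop = FALSE], dropped = dropped)
}

#' One-way repeated-measures ANOVA across conditions
#'
#' Classical within-subject decomposition with subjects as their own
#' controls: `F = MS_condition / MS_(condition x subject)` on
#' `(k - 1), (k - 1)(n - 1)` degrees of freedom, fitted via
#' `stats::aov(value ~ condition + Error(participant))`. Participants with
#' any missing condition cell are dropped listwise (and reported).
#'
#' @param summary_df output of [summarize_conditions()].
#' @param metric metric label carried into the result.
#' @param conditions conditions to compare (protocol order).
#' @return list with `metric`, `F`, `df_num`, `df_den`, `p`, `n`, `dropped`.
#' @export
rm_anova <- function(summary_df, metric = summary_df$metric[1],
                     conditions = CONDITIONS) {
  sw <- summary_wide(summary_df, conditions)
  m <- sw$matrix
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2) stop("repeated-measures ANOVA needs at least 2 complete participants")
  long <- data.frame(
    participant = factor(rep(rownames(m), times = k)),
    condition = factor(rep(colnames(m), each = n), levels = colnames(m)),
    value = as.vector(m))
  fit <- stats::aov(value ~ condition + Error(participant), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  ss_cond <- tab["condition", "Sum Sq"]
  ss_err <- tab["Residuals", "Sum Sq"]
  df_num <- tab["condition", "Df"]
  df_den <- tab["Residuals", "Df"]
  eps <- 1e-10 * (sum(long$value^2) + 1e-300)
  if (ss_err <= eps) {
    # degenerate: no within-subject error
    if (ss_cond <= eps) {
      F_stat <- 0; p <- 1
    } else {
      F_stat <- Inf; p <- 0
    }
  } else {
    F_stat <- (ss_cond / df_num) / (ss_err / df_den)
    p <- stats::pf(F_stat, df_num, df_den, lower.tail = FALSE)
  }
  list(metric = metric, F = F_stat, df_num = df_num, df_den = df_den, p = p,
       n = n, dropped = sw$dropped)
}

#' Pooled-SD Cohen's d
#'
#' `(mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)`; the sign follows the first
#' argument. Conventional magnitude labels: small ~0.2, medium ~0.5, large
#' > 0.8.
#'
#' @param mean1,sd1,mean2,sd2 group means and standard deviations.
#' @return Cohen's d (NA if both SDs are zero).
#' @export
cohens_d <- function(mean1, sd1, mean2, sd2) {
  pooled <- sqrt((sd1^2 + sd2^2) / 2)
  ifelse(pooled == 0, NA_real_, (mean1 - mean2) / pooled)
}

#' Label an effect size by conventional thresholds
#' @param d Cohen's d.
#' @return `"negligible"`, `"small"`, `"medium"` or `"large"`.
#' @export
effect_size_label <- function(d) {
  a <- abs(d)
  ifelse(is.na(a), NA_character_,
         ifelse(a > 0.8, "large",
                ifelse(a >= 0.35, "medium",
                       ifelse(a >= 0.1, "small", "negligible"))))
}

#' Bonferroni-corrected pairwise comparisons between conditions
#'
#' Paired two-sided t-tests for every pair of conditions, each raw p-value
#' multiplied by the number of pairs (10 for 5 conditions) and capped at 1,
#' with pooled-SD Cohen's d per pair. Degenerate pairs (zero-variance
#' differences) get an exact p of 1 (no difference) or 0 and are flagged.
#'
#' @param summary_df output of [summarize_conditions()].
#' @param metric metric label carried into the result.
#' @param conditions conditions to compare.
#' @return data.frame with one row per pair: means, mean difference, raw and
#'   Bonferroni p, Cohen's d, `degenerate` flag.
#' @export
bonferroni_pairwise <- function(summary_df, metric = summary_df$metric[1],
                                conditions = CONDITIONS) {
  sw <- summary_wide(summary_df, conditions)
  m <- sw$matrix
  k <- ncol(m)
  pairs <- utils::combn(colnames(m), 2, simplify = FALSE)
  n_comp <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    x <- m[, pr[1]]
    y <- m[, pr[2]]
    d <- x - y
    degenerate <- stats::sd(d) == 0
    if (degenerate) {
      p_raw <- if (mean(d) == 0) 1 else 0
    } else {
      p_raw <- stats::t.test(x, y, paired = TRUE)$p.value
    }
    data.frame(metric = metric, condition_a = pr[1], condition_b = pr[2],
               mean_a = mean(x), mean_b = mean(y), mean_diff = mean(d),
               p_raw = p_raw, p_bonferroni = min(1, p_raw * n_comp),
               cohens_d = cohens_d(mean(x), stats::sd(x),
                                   mean(y), stats::sd(y)),
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pre- vs post-fatigue comparison of a pulse-task metric
#'
#' Pulse trials exist only in the Pre-Fatigue condition and after the final
#' fatigue condition, so the comparison is a single paired t-test between
#' those two conditions, with pooled-SD Cohen's d.
#'
#' @param rows per-response metric rows (pulse responses).
#' @param metric metric column name.
#' @param n_first responses per participant entering the mean.
#' @return one-row data.frame (same columns as [bonferroni_pairwise()],
#'   without correction: a single planned comparison).
#' @export
pulse_comparison <- function(rows, metric, n_first = 5) {
  s <- summarize_conditions(rows, metric, n_first = n_first, task = "PULSE")
  out <- bonferroni_pairwise(s, metric,
                             conditions = c("PreFatigue", "Fatigue3"))
  out$p_bonferroni <- out$p_raw  # single planned comparison
  out
}
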