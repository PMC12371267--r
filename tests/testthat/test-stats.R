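# Condition summaries, repeated-measures ANOVA, pairwise comparisons and
# effect sizes.

test_that("condition summaries average the first five usable responses", {
  # values encode their own step index so the selection is visible
  rows <- fake_rows("P1", "PreFatigue",
                    value_fun = function(p, c, i) 100 + i)
  s <- summarize_conditions(rows, "rise_time_ms")
  expect_equal(s$value, mean(101:105))
  expect_equal(s$n_used, 5)
  expect_false(s$flagged)
  # with responses 2 and 4 excluded, responses 1,3,5,6,7 are used
  rows2 <- fake_rows("P1", "PreFatigue",
                     value_fun = function(p, c, i) 100 + i,
                     excluded_fun = function(p, c, i) i %in% c(2, 4))
  s2 <- summarize_conditions(rows2, "rise_time_ms")
  expect_equal(s2$value, mean(100 + c(1, 3, 5, 6, 7)))
  # all excluded: missing cell
  rows3 <- fake_rows("P1", "PreFatigue",
                     value_fun = function(p, c, i) 100 + i,
                     excluded_fun = function(p, c, i) TRUE)
  expect_equal(nrow(summarize_conditions(rows3, "rise_time_ms")), 0)
  # fewer than five available: flagged
  rows4 <- fake_rows("P1", "PreFatigue", n_steps = 3,
                     value_fun = function(p, c, i) 100 + i)
  expect_true(summarize_conditions(rows4, "rise_time_ms")$flagged)
})

test_that("summaries are invariant to input row order", {
  rows <- fake_rows(c("P1", "P2"), CONDITIONS,
                    value_fun = function(p, c, i) {
                      300 + 10 * match(c, CONDITIONS) + i
                    })
  a <- summarize_conditions(rows, "rise_time_ms")
  set.seed(3)
  b <- summarize_conditions(rows[sample(nrow(rows)), ], "rise_time_ms")
  expect_equal(a, b)
})

test_that("repeated-measures ANOVA matches hand-computed sums of squares", {
  m <- matrix(c(10, 12, 14,
                11, 14, 16,
                9, 11, 15), nrow = 3, byrow = TRUE,
              dimnames = list(c("P1", "P2", "P3"), c("A", "B", "C")))
  s <- data.frame(participant_id = rep(rownames(m), 3),
                  condition = rep(colnames(m), each = 3),
                  metric = "toy", value = as.vector(m))
  res <- rm_anova(s, "toy", conditions = c("A", "B", "C"))
  oracle <- hand_rm_anova(m)
  expect_equal(res$F, oracle$F, tolerance = 1e-10)
  expect_equal(res$p, oracle$p, tolerance = 1e-10)
  expect_equal(res$df_num, 2)
  expect_equal(res$df_den, 4)
  expect_equal(res$n, 3)
})

test_that("identical values across conditions give F = 0, p = 1", {
  s <- data.frame(participant_id = rep(c("P1", "P2", "P3"), 3),
                  condition = rep(c("A", "B", "C"), each = 3),
                  metric = "toy", value = rep(c(5, 7, 9), 3))
  res <- rm_anova(s, "toy", conditions = c("A", "B", "C"))
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
})

test_that("ANOVA requires at least two complete participants", {
  s <- data.frame(participant_id = "P1", condition = c("A", "B"),
                  metric = "toy", value = c(1, 2))
  expect_error(rm_anova(s, "toy", conditions = c("A", "B")), "at least 2")
})

test_that("incomplete participants are dropped listwise and reported", {
  s <- data.frame(participant_id = c("P1", "P1", "P2", "P2", "P3"),
                  condition = c("A", "B", "A", "B", "A"),
                  metric = "toy", value = c(1, 2, 3, 5, 9))
  res <- rm_anova(s, "toy", conditions = c("A", "B"))
  expect_equal(res$n, 2)
  expect_equal(res$dropped, "P3")
})

test_that("pairwise comparisons match hand-computed paired t-tests", {
  set.seed(42)
  m <- matrix(rnorm(15, mean = rep(c(10, 11, 13), each = 5)), ncol = 3,
              dimnames = list(paste0("P", 1:5), c("A", "B", "C")))
  s <- data.frame(participant_id = rep(rownames(m), 3),
                  condition = rep(colnames(m), each = 5),
                  metric = "toy", value = as.vector(m))
  pw <- bonferroni_pairwise(s, "toy", conditions = c("A", "B", "C"))
  expect_equal(nrow(pw), 3)
  # hand-computed paired t for the A-B pair
  d <- m[, "A"] - m[, "B"]
  t_stat <- mean(d) / (sd(d) / sqrt(5))
  p_raw <- 2 * stats::pt(-abs(t_stat), df = 4)
  row_ab <- pw[pw$condition_a == "A" & pw$condition_b == "B", ]
  expect_equal(row_ab$p_raw, p_raw, tolerance = 1e-12)
  expect_equal(row_ab$p_bonferroni, min(1, p_raw * 3), tolerance = 1e-12)
  # the correction never lowers a p-value
  expect_true(all(pw$p_bonferroni >= pw$p_raw))
})

test_that("degenerate pairwise comparisons are flagged with exact p", {
  m <- matrix(c(1, 2, 3, 1, 2, 3, 2, 3, 4), ncol = 3,
              dimnames = list(paste0("P", 1:3), c("A", "B", "C")))
  s <- data.frame(participant_id = rep(rownames(m), 3),
                  condition = rep(colnames(m), each = 3),
                  metric = "toy", value = as.vector(m))
  pw <- bonferroni_pairwise(s, "toy", conditions = c("A", "B", "C"))
  ab <- pw[pw$condition_a == "A" & pw$condition_b == "B", ]
  expect_true(ab$degenerate)
  expect_equal(ab$p_bonferroni, 1)  # identical columns
  ac <- pw[pw$condition_a == "A" & pw$condition_b == "C", ]
  expect_true(ac$degenerate)
  expect_equal(ac$p_raw, 0)  # constant non-zero difference
})

test_that("Cohen's d follows the pooled-SD definition", {
  expect_equal(cohens_d(1, 1, 0, 1), 1)
  expect_equal(cohens_d(3, 2, 3, 5), 0)
  expect_true(is.na(cohens_d(1, 0, 2, 0)))
  # the observed MVC drop: means 2.95 vs 2.20, SDs 0.58 and 0.47 give
  # d ~ 1.42 from the rounded values (1.43 reported from unrounded data)
  expect_equal(cohens_d(2.95, 0.58, 2.20, 0.47), 1.42, tolerance = 0.005)
  expect_equal(effect_size_label(cohens_d(2.95, 0.58, 2.20, 0.47)), "large")
  expect_equal(effect_size_label(0.05), "negligible")
  expect_equal(effect_size_label(-0.5), "medium")
})

test_that("shuffling condition labels preserves the null F distribution", {
  # permutation sanity check on a null table: the observed F should not be
  # extreme among label-permuted Fs
  set.seed(7)
  m <- matrix(rnorm(30, mean = rep(rnorm(6, 10, 2), 5)), nrow = 6,
              dimnames = list(paste0("P", 1:6), paste0("C", 1:5)))
  to_df <- function(mm) data.frame(
    participant_id = rep(rownames(mm), ncol(mm)),
    condition = rep(colnames(mm), each = nrow(mm)),
    metric = "toy", value = as.vector(mm))
  obs <- rm_anova(to_df(m), "toy", conditions = paste0("C", 1:5))$F
  perm <- replicate(60, {
    mp <- t(apply(m, 1, sample))
    colnames(mp) <- colnames(m)
    rm_anova(to_df(mp), "toy", conditions = paste0("C", 1:5))$F
  })
  expect_gt(mean(perm >= obs), 0.05)
})

test_that("the pulse comparison is a single planned pre/post contrast", {
  rows <- fake_rows(c("P1", "P2", "P3"), c("PreFatigue", "Fatigue3"),
                    value_fun = function(p, c, i) {
                      140 + 10 * (c == "Fatigue3") + i +
                        5 * match(p, c("P1", "P2", "P3"))
                    })
  rows$task <- "PULSE"
  pc <- pulse_comparison(rows, "rise_time_ms")
  expect_equal(nrow(pc), 1)
  expect_equal(pc$condition_a, "PreFatigue")
  expect_equal(pc$condition_b, "Fatigue3")
  expect_equal(pc$p_bonferroni, pc$p_raw)
  expect_equal(pc$mean_diff, -10, tolerance = 1e-9)
})
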