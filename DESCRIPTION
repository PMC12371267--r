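Package: legforce
Title: Analysis of Leg External-Force Control Under Neuromuscular Fatigue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for characterizing how well the human leg controls the
    vertical ground-reaction force it exerts, and how that control degrades
    with neuromuscular fatigue. The package segments force-matching trials
    (step, pulse, hold and maximum-voluntary-contraction tasks) into
    onset-aligned responses, computes step-response characteristics
    (10-90% rise time, bandwidth, fall time, overshoot, steady-state error
    and variability), tracks isometric force steadiness (coefficient of
    variation in 1-s windows) and surface-EMG median-frequency fatigue
    indices (2-s FFT windows), applies response exclusion rules, and runs
    the condition-level statistics (one-way repeated-measures ANOVA,
    Bonferroni-corrected pairwise comparisons, pooled-SD Cohen's d). A
    synthetic-data generator simulates the full experimental protocol with
    a delayed second-order force plant, signal-dependent noise and
    programmable fatigue effects, so the entire pipeline is verifiable
    against ground truth without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
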