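---
title: "Measuring leg force-control responsiveness and its loss under fatigue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring leg force-control responsiveness and its loss under fatigue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

When a person standing on one leg tries to match a visual force target by
pushing against a force plate, the vertical ground-reaction force they
produce behaves like the output of a feedback controller: it rises toward
the target with some delay, may overshoot, settles, and fluctuates around
the target. `legforce` quantifies that behavior with the classical
step-response vocabulary — **rise time** (10% to 90% of the step
amplitude), **bandwidth** (0.35 / rise time in seconds, the usual
first-order approximation of the highest target frequency the controller
could track), **fall time** (90% to 10%), **overshoot** (signed peak excess
as a percent of the step), **steady-state error** and **steady-state
variability** (mean offset and coefficient of variation once settled) —
and tracks two complementary fatigue markers: the coefficient of variation
of force during sustained holds, and the median frequency (MDF) of the
surface EMG power spectrum, which compresses toward lower frequencies as a
muscle fatigues.

The experimental protocol the package analyzes has five conditions
(Training, Pre-Fatigue, then three fatigue stages), each probing control
with four task types: maximal pushes against an unattainable 5-BW target
(MVC, 10 s), 73-s holds at body weight plus 25% of the pre-fatigue MVC
(the fatiguing task), square waves of ten 1.0 → 1.4 BW steps (4 s up, 3 s
down), and trains of ten 0.05-s pulses to 1.4 BW. Forces are normalized to
body weight (BW); force is sampled at 1000 Hz and EMG at 2000 Hz.

## Analysis conventions

All analysis constants live in `default_config()` and can be overridden
from YAML; the defaults are the protocol's published constants, so the
zero-override run is the canonical analysis.

* **Filtering.** Force is low-pass filtered with a fourth-order 10 Hz
  Butterworth — the same filter applied to the displayed feedback signal —
  before any metric is computed. Whether the original metrics were taken
  from the displayed (filtered) or raw signal is not stated in the
  protocol; we default to the filtered signal because that is the signal
  participants actually saw and controlled, with `force_filter.enabled:
  false` available to analyze raw force. The filter is applied zero-lag
  (forward-backward, magnitude response squared) so response-timing
  metrics carry no group delay, with reflective padding of three settling
  lengths so the filter transient stays outside the first analysis
  window. EMG is band-passed 30–400 Hz and band-stopped 59–61 Hz (both
  fourth-order zero-lag Butterworth), and each channel is shifted back
  onto the force clock by linear interpolation to undo the 500 µs wireless
  transmission delay.
* **Segmentation.** Step trials are cut into ten 6-s segments (1 s before
  each target step-up to 1 s after the step-down), pulse trials into ten
  3-s segments (1.5 s either side). Onsets always come from the target
  waveform metadata — the commanded step times — never from the force
  signal.
* **Thresholds and crossings.** Rise/fall thresholds are `baseline +
  0.1 × step` and `baseline + 0.9 × step` (1.04 and 1.36 BW for the
  default task). Crossing times are the *first* crossings inside the
  search window, located by linear interpolation between samples: this is
  deterministic, robust to resampling (the test suite checks agreement
  with a 100 kHz brute-force search to better than 1 ms) and matches
  control-engineering convention. Rise metrics search from 0.5 s before
  the step-up to 1 s after; steady-state windows run from 2 to 4 s after
  the onset (the step lasts 4 s); the fall window spans segment seconds
  4–6, bracketing the step-down. All windows are half-open `[start, end)`
  on the segment clock, and every metric is invariant to shifting the
  segment's time origin.
* **Exclusions.** A step response is excluded when it (1) steps up half a
  second or more before the target, (2) has not begun to step up within
  half a second after the target, (3) already sits above 10% of the step
  during the pre-onset half second (judged on the window mean), or (4)
  steps down a second or more before the target does. Pulse responses are
  excluded for rising more than 0.25 s early or for not falling back
  below the 10% threshold until more than 0.5 s after the pulse ends.
  "Steps up" / "steps down" are operationalized as crossings of the same
  10% threshold the rise-time metric uses, so the exclusion rules
  introduce no new constant family. For criterion (2) we deliberately use
  the 10% threshold (the response has not *begun* to rise), not the 90%
  threshold: with the observed latencies — rise times above 300 ms plus a
  visuomotor delay on the order of 150 ms — a 90%-within-0.5-s rule would
  exclude the majority of perfectly ordinary responses, which is
  incompatible with the protocol's overall exclusion count of 11 out of
  roughly 2700 responses.
* **Statistics.** For every condition, each participant's metric value is
  the mean of the **first five non-excluded step responses** following
  the condition's final MVC, in trial order; excluded responses do not
  count toward the five (the alternative — counting and discarding them —
  is not stated in the protocol, and the non-excluded-first-five rule is
  the documented choice here). Condition effects are tested with a
  one-way repeated-measures ANOVA (`F = MS_condition / MS_(condition ×
  subject)`), missing cells handled by listwise deletion (logged). No
  sphericity correction is applied by default since the original analysis
  reports none. Significant omnibus effects are followed by paired
  two-sided t-tests on all 10 condition pairs with Bonferroni correction
  (p × 10, capped at 1); effect sizes are pooled-SD Cohen's d,
  `(m1 − m2) / sqrt((sd1² + sd2²)/2)`. The pulse task exists only before
  and after fatigue, so its comparison is a single planned paired t-test.
  Degenerate cases are handled explicitly: zero within-subject error
  yields F = 0, p = 1 when condition means agree (and F = ∞, p = 0 when
  they do not); zero-variance pairwise differences are flagged and given
  exact p of 1 or 0.
* **EMG spectra.** MDF is computed per non-overlapping 2-s window from a
  single-taper periodogram (0.5 Hz resolution), band-limited to
  30–400 Hz; the windowing details of the original FFT analysis are
  unstated, and the plain periodogram is the simplest defensible default
  (Welch averaging sits behind `emg.estimator`). The median is located by
  interpolating the cumulative power from both ends of the band and
  averaging, so a spectrum of two equal lines splits at their midpoint.
  The fatigue index compares the first 10 s of the first fatiguing hold
  with the final 10 s of the last hold of each condition, as the mean of
  the corresponding five windows, and per-participant percent changes
  are averaged (mean of ratios, matching the reported summaries).

## The synthetic participant

The generator exists so that every stage of the pipeline can be verified
against ground truth. The simulated "participant" is deliberately the
simplest system whose descriptors are exactly the metrics above: a pure
visuomotor delay followed by a linear second-order low-pass tracking the
commanded target, saturated at the participant's maximum force, plus
signal-dependent Gaussian noise (SD proportional to the instantaneous
noiseless force) and a slow drift. Two parameters map one-to-one onto the
measured quantities — the natural period sets rise time, the damping ratio
sets overshoot — and multiplicative noise makes a programmed noise-scale
factor equal the expected measured CV ratio. This is an artifact choice,
not a claim about the nervous system: the study itself fits no controller
model.

The discretization is exact: the second-order system is converted to a
difference equation by eigendecomposition-based zero-order-hold at the
trace's sampling rate, so a noise-free run equals the closed-form analytic
step response at every sample to machine precision (the test suite
requires 1e-6 BW RMS; the implementation achieves ~1e-12). Matrix-
exponential approximations were rejected because their ~1e-8 coefficient
error compounds visibly over a 73-s recursion.

Pulse targets need a separate pathway. A linear tracker literally
following a 0.05-s command barely moves (a few percent of the step), yet
real participants produce near-full-amplitude pulses — the brief target
elicits a pre-planned ballistic push rather than feedback tracking. Pulse
trials therefore track an internal command widened to 0.22 s through a
faster (natural period × 0.49), shorter-latency (50 ms) pathway. That
pathway is deliberately insensitive to the fatigue profile, mirroring the
study's finding that pulse responsiveness resists fatigue.

**Defaults and calibration.** The default plant (natural period 0.732 s,
damping 0.835, delay 150 ms, noise CV 4.68%, drift 2e-5 BW/s, maximum
2.95 BW) was calibrated once, in a pilot run of this package's own
pipeline, so that a default synthetic study reproduces the study's
pre-fatigue magnitudes: ~303 ms rise time, ~4.3% overshoot, ~0.61%
hold-task CV, ~148 ms pulse rise time, 2.95 BW MVC. The noise CV is
specified pre-filter; the 10 Hz display filter attenuates wide-band
multiplicative noise by a factor of ~7.8, which the calibration folds in.
Between-participant spread uses a normal MVC (SD 0.58 BW) and mean-one
log-normal multipliers on the natural period (log-SD 0.30) and noise
level (log-SD 0.45), matching the reported between-participant spreads of
MVC, rise time and hold CV. The fatigue profile defaults program the
reported effect magnitudes — MVC × 0.739 (a 26.1% drop), natural period
× 1.233 on step trials (rise-time slowing), hold-noise × 4.6, EMG band
shift × 0.897 (~10.3% MDF compression) by the final condition, approached
progressively through the intermediate conditions. The EMG generator
shapes white noise into per-muscle bands (e.g. 66–186 Hz for the lateral
gastrocnemius, centering its baseline MDF near 126 Hz), amplitude-
modulated by force; within fatiguing holds the band shift ramps linearly
in 2-s blocks aligned with the MDF analysis windows.

One protocol note: the generator inserts a practice hold in the
Pre-Fatigue block. The condition-level hold-variability comparison needs a
pre-fatigue baseline hold, and the protocol's own baseline ("a practice
Hold Task" before fatigue) is otherwise absent from the task sequence.

**What the generator does not emulate.** No motor-unit, Hill-type or
musculoskeletal structure; no learning or strategy changes across
conditions (the Training condition differs from Pre-Fatigue only through
sampling noise); symmetric rise and fall dynamics (observed falls are
slower than rises); no asymmetric or heavy-tailed noise; EMG channels are
mutually independent and spectrally flat within their bands, and all six
muscles share one programmed MDF shift although the study found
muscle-specific declines. Passing tests on synthetic sessions therefore
demonstrate that the *pipeline* measures what it claims to measure — not
that the plant is a faithful physiological model.

## Pre-registered verification bands

The acceptance suite fixes its tolerances ahead of time:

* *Definitional exactness*: a synthetic noiseless response with an exact
  1.000-s 10–90% rise must return 0.35 Hz bandwidth (to the printed
  precision), and `bandwidth × rise time = 0.35` must hold for every
  computed pair (1e-12).
* *Oracle equivalence*: rise/fall within 1 ms and overshoot within 0.1
  percentage points of a 100 kHz dense-resampling threshold search over
  100 random plants; MDF within one periodogram bin (0.5 Hz at 2-s
  windows) of a cumulative-sum brute force over 100 random segments;
  ANOVA and Bonferroni results equal to hand-computed sums of squares and
  t-tests on toy tables.
* *Programmed-effect recovery* (means over 20 seeded sessions): MVC
  decline within 26.1 ± 1 percentage points; rise-time ratio within
  [1.15, 1.35] (programmed 1.233); hold-CV ratio within ±15% of 4.6;
  MDF decline within 10.3 ± 2 percentage points. The ANOVA must detect
  the programmed rise-time effect at α = 0.05 in at least 80% of 20
  simulated 18-participant studies.
* *Headline reproduction* (one default 18-participant study): each
  pre-fatigue group mean must lie within three standard errors of the
  reported mean, taking the reported between-participant SD over √18 —
  e.g. rise time 303 ± 71 ms, bandwidth 1.33 ± 0.42 Hz, overshoot
  4.30 ± 1.85%, MVC 2.95 ± 0.41 BW, hold CV 0.61 ± 0.22%, pulse rise
  148 ± 45 ms, and a 26.1 ± 8.7% MVC decline.
* *Statistical calibration*: the ANOVA's type-I error over 2000 simulated
  null tables (n = 18, k = 5, additive subject offsets) must lie in
  [0.035, 0.065].

Problem sizes were chosen to keep the full verification run on a single
CPU in well under half an hour: 100 random segments per oracle family, 20
seeds per recovery band, one 18-participant study for the headline check
and 2000 null tables for calibration.

## Known limitations

* Bandwidth is reported per response and averaged, so mean bandwidth
  exceeds 0.35 over the mean rise time (Jensen's inequality); the
  synthetic study reproduces the reported mean bandwidth only to the
  extent that its between-participant rise-time spread matches the real
  one.
* The measured overshoot of a noisy response is peak-based and therefore
  biased upward by roughly two post-filter noise SDs; the calibration
  compensates at the default noise level, but overshoot comparisons
  across very different noise levels inherit the bias.
* The exclusion rules' numeric operationalization (10% threshold family)
  is a documented choice; the study's printed exclusion count cannot
  discriminate between nearby operationalizations.
* The Zenodo deposit of the original recordings is not parsed by this
  package; `run_pipeline()` consumes the documented CSV + JSON trial
  contract, and a converter for the deposit's (undocumented) layout would
  be a separate, best-effort utility.
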