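---
title: "Smartwatch heart-rate biomarkers: models, generator design, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smartwatch heart-rate biomarkers: models, generator design, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearhr)
```

## The problem

A wrist-worn photoplethysmography (PPG) watch reports a heart-rate (HR)
estimate roughly every 10 minutes (more often during physical activity) and
stores sleep-state *changes* (awake / light / deep). In a small
parallel-group trial — here emulated at 12 subjects, 4 placebo and 8 active,
six baseline days (−6..−1) and seven dosing days (0..6) with the active dose
titrated 20, 40, then 80 µg/day — such a stream can act as an at-home
cardiovascular biomarker, provided two properties are quantified:

* **repeatability** — how stable a daily summary is across baseline days,
  expressed as an intraclass correlation (ICC), and the resulting
  **minimum detectable effect** (MDE);
* **sensitivity** — whether dosing-day levels depart from the averaged
  baseline, with multiplicity control and standardised effect sizes.

`wearhr` implements the full chain and a synthetic data generator whose
ground truth is known, so the chain is validated by parameter recovery
rather than by re-reading any particular dataset.

## Segmentation rules

The night attributed to study day *d* is searched in the noon-to-noon window
[12:00 of *d*, 12:00 of *d*+1): it starts at the first event with a
non-awake state and ends at the last state-change event in the window (the
terminal transition, normally back to awake). Nights with no non-awake
event are *missing*; intervals shorter than 3 hours are *excluded* from the
asleep analysis. Asleep samples are those inside the closed interval
[start, end]; a sample exactly on a boundary is asleep (a deterministic
tie-break). Awake samples lie strictly between the previous night's end and
the current night's start; when a bounding night is missing, that bound
falls back to a 9 AM / 9 PM clock window (and the day is flagged
`default_window`). Short nights still bound their neighbouring awake days —
only their asleep series is dropped. These rules are verified against an
independent per-sample brute-force classifier on randomly generated toy
days.

## Markers

Each subject-day-period segment is reduced to its 2.5th, 50th and 97.5th
percentiles (Low / Median / High). Percentiles use linear interpolation
between closest ranks with index *h* = (*n*−1)*p* — the "type 7" convention
that is the default of mainstream numeric stacks; the ICC and MDE
conclusions are insensitive to the convention, and a property test pins the
implementation to an independent sorting oracle. No minimum sample count is
imposed beyond non-emptiness; `n_samples` is recorded so users can filter.

## Repeatability model

Per marker, predose values are fit by REML (`nlme::lme`) as
$$y_{id} = \mu + \delta_d + b_i + \varepsilon_{id},\qquad
b_i \sim N(0,\sigma^2_b),\ \varepsilon_{id} \sim N(0,\sigma^2_w),$$
with day categorical (sum-to-zero coding, so the intercept is the marker
mean across days and marginal type III F tests are well defined). Then

* ICC $= \sigma^2_b/(\sigma^2_b+\sigma^2_w)$, clamped to [0, 1] (REML
  boundary estimates are truncated at 0);
* MDE $= (t_{1-\alpha/2,\,n-1} + t_{\text{power},\,n-1})\,
  \sigma_{\text{total}}\sqrt{2/n}$, with
  $\sigma_{\text{total}} = \sqrt{\sigma^2_b+\sigma^2_w}$, defaults
  $\alpha=.05$, power $=.80$, $n=12$. The $\sqrt{2/n}$ two-sample form is
  the default because the design is parallel-group; a paired form
  ($\sqrt{1/n}$) is exposed as an option. "Inverse sample size calculation"
  admits both readings; the choice is pinned here for testability.
* a type III F test for the day term (numerator df = number of day levels
  − 1, i.e. 5 for the six predose days).

**Degrees of freedom.** Denominator df use nlme's between-within
(containment) approximation rather than Kenward–Roger. KR is not portable
across numeric stacks; with 12 subjects and ~6–13 days the two differ in
the second decimal of p-values and in no qualitative conclusion. None of
the package's validation quantities depend on the denominator df choice
except the family-wise error simulation, where the containment-df p-values
are empirically uniform (KS test in the suite).

The REML fit is checked against the closed-form ANOVA method-of-moments
estimator on balanced data ($\hat\sigma^2_w = MS_W$,
$\hat\sigma^2_b = (MS_B - MS_W)/k$) to 1e-6 in interior cases, and against
its generating values in large-sample recovery tests.

## Treatment model, contrasts, effect sizes

Over all days, `y ~ day * arm` with the subject random intercept. For each
arm and each dosing day *d*, the baseline contrast puts weight +1 on day
*d*'s estimated marginal mean and −1/6 on each predose day's, within arm.
Contrast SEs come from the fixed-effect covariance; p-values use the t
distribution with the interaction term's containment df. The Bonferroni
family is the 14 contrasts of one marker model (7 dosing days × 2 arms);
adjusted p-values are stored as min(1, 14·p) and only *displayed* capped at
.99. Cohen's d divides the contrast by the total SD of the same treatment
model (not the predose model). Contrast estimates and SEs are pinned to
`emmeans` in a cross-check test, and their unbiasedness and family-wise
error control are verified by simulation.

One bias is worth knowing about: the plug-in d (contrast divided by the
square root of *estimated* total variance) is upward-biased in small
samples — with 12 subjects the between-subject component carries ~11 df and
Jensen's inequality inflates the mean estimated d by about 3.5% (e.g. a
true 2.75 is estimated at ≈2.85 on average). The package reports the
estimator as defined; the recovery tests document the bias rather than
correcting it away.

The same fixed/random structure applied to nightly durations
(`sleep_duration_model()`) gives the treatment F tests and the
sleep-duration ICC.

## The synthetic generator

`simulate_cohort()` emulates, per subject and day:

* a night: onset ~ 23:30 clock time (SD 45 min), duration ~ N(6.5 h,
  0.75 h total SD) split into a per-subject habitual shift and
  night-to-night noise via `sleep_duration_icc` (default 0.64, so the
  sleep-duration analysis has realistic repeatability); the watch emits
  light/deep alternations and a terminal awake event. With probability 0.1
  a night reports no events (sleep still *happens* — HR follows asleep
  physiology; only the record is missing), and with probability 0.02 it is
  truncated below 3 h.
* an HR stream on a 10-minute grid, with one ~28-minute daytime activity
  burst sampled at 2-minute cadence. These defaults make the expected
  counts ≈ 39 asleep and ≈ 116 awake samples per patient-day, matching the
  observed per-day availability the generator is calibrated to.
* sample values: period mean (75.4 awake / 63.2 asleep bpm) + subject
  intercept (SD 4.58 bpm, calibrated to a between-subject variance of
  ~21 bpm²) + a per-(day, period) within-subject shift (SD 3 bpm, so
  day-to-day marker variance is ~9 bpm² and the asleep-median ICC ≈ 0.70)
  + a single-sinusoid circadian term (amplitude 2 bpm, peak 15:00) +
  sample noise (SD 5 bpm). The active arm additionally receives a
  (day, period) shift following the titration-shaped default effect
  profile; awake and asleep effects may differ.

All timestamps live in one fixed study timezone (UTC), with no DST
transitions. Noise is Gaussian throughout — deliberately matching the
analysis model so that recovery tests are well-posed. `simulate_marker_table()`
bypasses the raw-stream stages and generates directly from the
random-intercept model, which is what the statistics-stage recovery tests
and the acceptance script consume.

**What the generator does not emulate.** No PPG waveform or accelerometry;
no device wear-time or battery behaviour; the activity-burst trigger and
cadence of the real device are undocumented, so the burst model is a
count-calibrated stand-in, not a device emulation; HR distributions in real
streams are skewed with movement artefacts, whereas the generator is
Gaussian. Passing recovery tests therefore demonstrate that the *pipeline*
is correct and well-calibrated under the stated model, not that any
particular device meets these operating characteristics.

## Numerical choices and degenerate inputs

* REML optimizer tolerance 1e-8; a non-converged fit is returned flagged
  and every downstream operation refuses it (exactly constant data, e.g.
  all noise off, is reported as non-convergence rather than a fake fit).
* A single subject (between-subject variance unidentifiable) or a single
  day level is an error at fit time.
* `icc()` errors when total variance is zero; otherwise clamps to [0, 1].
* Empty HR files are empty streams, not errors; unknown sleep states and
  malformed timestamps are parse errors naming the line.
* Duplicate (subject, timestamp) rows collapse to the last occurrence.
* HR values are clamped to the physiologically plausible (20, 250) bpm
  device range.

## Validation problem sizes

The suite validates recovery at the trial's own scale: 200 replicate
studies for ICC recovery (generating ICCs 0.70 / 0.64 / 0.23) and for
Cohen's d recovery, 500 replicates for the family-wise error rate and for
F-test size/uniformity checks, 1000 simulated patient-days for the
sample-count calibration, and 2000 subjects for large-sample variance
recovery — sizes at which Monte-Carlo standard errors are small relative to
the tolerances being asserted, while the whole suite stays comfortably
fast.

## Limitations

* Denominator df are containment, not Kenward–Roger (second-decimal
  p-value differences at this scale).
* The percentile-of-percentile MDE ratio (`mde_pct`) is defined against the
  model-estimated marker mean; other mean definitions change the ratio in
  the first decimal.
* No imputation: missing nights and missing HR samples simply thin the
  (unbalanced) mixed-model fits.
* At most one sleep interval per noon-to-noon window (no nap detection);
  light-vs-deep substates are carried through ingestion but not analysed.
* No bootstrap confidence intervals for the ICC.
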