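# wearhr

Wrist-worn smartwatches estimate heart rate (HR) from photoplethysmography
every few minutes, around the clock, at home. Before such a stream can serve
as a drug-trial biomarker, two questions must be answered: how *repeatable*
are summaries of the stream from day to day, and how *sensitive* are they to
a true pharmacological change? `wearhr` implements a complete pipeline for
answering both in small parallel-group trials, together with a synthetic
smartwatch-data generator with known ground truth so every stage can be
validated by parameter recovery.

The pipeline:

1. **Ingest & segmentation.** HR samples and sleep-state *change* events
   (awake/light/deep) are read from CSV. For each study day, the night is
   reconstructed from the first non-awake event to the last state change in
   a noon-to-noon window; asleep series shorter than 3 h and nights without
   any sleep state are excluded. Awake samples are everything outside the
   asleep boundaries (9 AM–9 PM fallback when sleep states are missing).
2. **Markers.** Each subject-day-period segment is summarised by its 2.5th,
   50th and 97.5th percentiles — six markers: Awake/Asleep × Low/Median/High.
3. **Repeatability.** Per marker, the predose days (−6..−1) are fit with the
   random-intercept linear mixed model (REML)

   `y_id = μ + day_d + b_i + ε_id,  b_i ~ N(0, σ²_b),  ε_id ~ N(0, σ²_w)`

   giving the intraclass correlation **ICC = σ²_b / (σ²_b + σ²_w)**, a
   type III F test for structural day effects, and the minimum detectable
   effect **MDE = (t₁₋α/₂,ₙ₋₁ + t_power,ₙ₋₁) · σ_total · √(2/n)** with
   σ_total = √(σ²_b + σ²_w), α = .05, power = .80, n = 12.
4. **Treatment sensitivity.** Over all days, `y ~ day * arm` with a subject
   random intercept; each dosing day's estimated marginal mean is contrasted
   against the average predose level within arm, Bonferroni-corrected over
   the 14 day×arm contrasts, and standardised into Cohen's
   **d = contrast / √(σ²_b + σ²_w)**. The same model applied to nightly
   sleep durations checks that treatment does not disturb sleep itself.

## Worked example

```r
library(wearhr)

cfg <- pipeline_config(generator = generator_config(seed = 42))
dir <- tempfile(); simulate_to_csv(cfg, dir)        # hr.csv, sleep.csv, allocation.csv
out <- tempfile()
res <- run_pipeline(file.path(dir, "hr.csv"), file.path(dir, "sleep.csv"),
                    file.path(dir, "allocation.csv"), out, cfg)
res$repeatability[, c("period","marker","mean_bpm","icc","mde_bpm","mde_pct","f_day","p_day")]
```

```
  period marker mean_bpm   icc mde_bpm mde_pct f_day p_day
1 asleep    low     55.7 0.618    6.13   11.01 0.602 0.699
2  awake    low     69.7 0.718    6.45    9.25 1.509 0.202
3 asleep median     64.8 0.636    6.08    9.38 0.901 0.489
4  awake median     79.4 0.724    6.55    8.24 1.448 0.222
5 asleep   high     73.5 0.586    6.31    8.58 1.244 0.305
6  awake   high     89.1 0.684    6.74    7.56 0.922 0.474
```

Each row is one marker over the six predose days: its estimated mean (bpm),
repeatability (ICC), the smallest parallel-group difference detectable with
12 subjects (MDE, absolute and relative to the mean), and the day F test
(no structural day effect in this null baseline, as expected). The dosing-day
contrasts for the asleep-median marker in the active arm track the titrated
effect the generator injected (20 → 40 → 80 µg):

```r
ct <- res$contrasts
ct[ct$period == "asleep" & ct$marker == "median" & ct$arm == "active" & ct$day <= 3,
   c("day", "estimate_bpm", "se_bpm", "p_adj")]
```

```
 day estimate_bpm se_bpm    p_adj
   0         2.30   1.25 9.48e-01
   1         9.29   1.25 3.97e-10
   2         9.89   1.33 3.78e-10
   3        16.65   1.25 3.90e-23
```

A small change on the first dosing day is not yet significant after
Bonferroni correction; from day 1 onward the elevation is unambiguous.
The closed-form MDE is available directly:

```r
mde(5.446, n = 12)
#> MDE = 6.84 bpm  [sd = 5.446, n = 12, alpha = 0.05, power = 0.80, two_sample]
```

A command-line front end (`inst/cli/wearhr.R`) wraps the same functions:
`simulate`, `run` and `recover` subcommands with a YAML config.

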