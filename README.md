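# bilatacc

Bilateral wrist-accelerometry analysis for stroke rehabilitation.

After a stroke with unilateral arm weakness, recovery is usually tracked
with clinician-rated scales — the modified Motor Assessment Scale (M-MAS,
0–15 for the affected arm) — and patient self-report — the Motor Activity
Log (MAL; Amount-of-Use and Quality-of-Movement subscales, each 0–5).
Wrist-worn accelerometers, one per wrist over a 24 h day at the start (T1)
and end (T2) of rehabilitation, offer an objective complement. `bilatacc`
turns the raw bracelet exports into per-arm activity metrics and relates
them to the clinical scores. It is aimed at rehabilitation researchers
working with bilateral wrist sensor data, and ships a seeded synthetic
cohort generator so the entire pipeline is testable without patient data.

## The method

For each arm, raw signed 8-bit counts *c* at 32 Hz (64 counts = 1 g =
9.82 m/s²) are processed as

1. scaling: *a = c · 9.82 / 64* m/s²;
2. 5th-order Butterworth high-pass at 3 Hz, applied per axis (removes
   gravity and posture before the norm can fold them in);
3. signal vector magnitude *‖(aₓ, a_y, a_z)‖₂*;
4. 96-sample moving average, subsampled every 48 samples → 0.67 Hz.

The two arms are synchronized by the integer lag (±90 s search) minimizing
their mean absolute difference over the overlap, trailing idle runs
(bracelet left on a table) are trimmed, and both arms are cropped to a
common support. Time-aligned sample pairs are ranked by the bilateral sum
`left + right`; the top 10 % (≈ the most active 2.5 h of a 24 h day) define
each arm's session acceleration as the mean magnitude over that set, and

```
asymmetry = (right − left) / (right + left)
```

identifies the weaker side by sign. Cohort analysis reports per-occasion
medians and quartiles, per-patient T2 − T1 deltas, and Spearman rank
correlations (mid-ranks; exact permutation p for n ≤ 9, t-approximation
above) of affected-arm acceleration against MAS, MAL-AoU and MAL-QoM at
T1, T2 and for the deltas.

## Worked example

Simulate a 12-patient cohort (0.5 h sessions to keep the example quick;
the generator's study-scale default is 24 h) and run the full pipeline:

```r
library(bilatacc)

dir <- file.path(tempdir(), "demo")
params <- synth_params(n_patients = 12, duration_h = 0.5,
                       trailing_idle_range_s = 120, sync_offset_range_s = 10)
sim <- simulate_cohort(params, dir, seed = 42)

config <- default_config(cohort_file = sim$cohort_file,
                         out_dir = file.path(dir, "out"))
config$bilateral$trim.min_run_s <- 60       # idle tails are ~1-2 min here
config$bilateral$session.min_overlap_h <- 0.1
config$bilateral$sync.max_lag_s <- 30
res <- run_pipeline(config)

subset(res$table3, contrast == "T1")
#>    score contrast       rho      p_value  n          method
#>      mas       T1 0.8998368 6.696957e-05 12 t-approximation
#>  mal_aou       T1 0.9071818 4.634685e-05 12 t-approximation
#>  mal_qom       T1 0.9422081 4.605617e-06 12 t-approximation

subset(res$table2, variable == "mean_affected")
#>  session      variable    median        q1        q3  n
#>       T1 mean_affected 0.5627083 0.4414649 0.8622916 12
#>       T2 mean_affected 0.6430439 0.5035566 0.9880656 12
```

At T1 the affected arm's acceleration correlates strongly and positively
with every clinical score — the generator couples sensor output and scores
through a common latent motor ability, and the pipeline recovers that
coupling. The descriptive rows give the cohort's median (Q1–Q3)
affected-arm acceleration in m/s² per occasion. Per-session summaries are
in `res$summaries`:

```r
s <- res$summaries[1, ]
cat(sprintf("patient %s %s: affected %.2f, unaffected %.2f m/s^2, asymmetry %+.2f\n",
            s$patient_id, s$session, s$mean_affected, s$mean_unaffected,
            s$asymmetry_index))
#> patient P01 T1: affected 0.84, unaffected 0.95 m/s^2, asymmetry +0.06
```

This patient's affected (left) arm moves less than the right, so the
asymmetry index is positive — the sign convention that places left-weak
patients below the left/right symmetry line in a bilateral scatter
(`res$fig1_points`). The pipeline writes `table2.csv`, `table3.csv`,
`deltas.csv`, `fig1_points.csv` and a `manifest.json` (configuration hash
plus every excluded patient and reason) to the output directory. A thin
command-line wrapper with `simulate` and `run-all` verbs is installed at
`inst/cli/bilatacc.R`.

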