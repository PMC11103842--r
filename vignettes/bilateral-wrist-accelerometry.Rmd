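---
title: "Bilateral wrist accelerometry: processing model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilateral wrist accelerometry: processing model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilatacc)
```

## The problem

After a stroke with unilateral arm weakness, recovery of arm motor function
is usually tracked with clinician-rated scales (the modified Motor
Assessment Scale, M-MAS, 0–15 for the affected arm) and patient self-report
(the Motor Activity Log, MAL, with Amount-of-Use and Quality-of-Movement
subscales, each a 0–5 mean over 30 daily activities). Wrist-worn
accelerometers offer an objective complement: a patient wears one bracelet
per wrist for 24 h at the start (T1) and end (T2) of an inpatient
rehabilitation period, and the recorded movement of the affected arm — and
its asymmetry against the unaffected arm — is compared with the clinical
scores. `bilatacc` implements that comparison as a reusable, tested
pipeline, plus a synthetic-cohort generator so every stage can be validated
without access to patient data.

## The processing model

Each recording is a triaxial stream of signed 8-bit counts at a nominal
32 Hz, with 64 counts equal to one Earth gravity taken as 9.82 m/s². The
per-arm chain is, in order:

1. **Count scaling.** `a = count × 9.82 / 64` m/s². Counts outside
   \[−128, 127\] are an error, never clipped: silent clipping would bias
   every downstream mean.
2. **High-pass filtering, per axis.** A 5th-order Butterworth high-pass at
   3 Hz removes gravity and posture. Filtering precedes the norm — in the
   reverse order the norm would fold the gravity vector into the magnitude
   and the filter could no longer remove it.
3. **Signal vector magnitude.** The per-sample Euclidean norm of the three
   filtered axes; orientation information is deliberately discarded.
4. **Smoothing and decimation.** A 96-sample moving average subsampled
   every 48 samples: output `k` is the mean of the half-open block
   `[48k, 48k + 96)`, the output rate is 32/48 ≈ 0.67 Hz, and each output
   is stamped at its window center. Tail samples that do not fill a window
   are dropped, so the output length is exactly
   `floor((n − 96)/48) + 1`.

The two arms are then synchronized: the bracelets are powered on at
slightly different times, so an integer lag on the decimated grid is chosen
by exhaustive search (default ±90 s) to minimize the **mean** absolute
difference between the arms over their overlap. Trailing idle runs — the
bracelet left running on a table — are trimmed when a terminal run below
0.01 m/s² lasts at least 300 s; leading segments are never trimmed, and
both arms are cropped to their common support.

Finally, time-aligned sample pairs are ranked by the *sum* of the two arms'
magnitudes and the top 10 % (k = ⌈0.1 n⌉, ties to the earlier timestamp)
are kept — for a 24 h recording, roughly the most active 2.5 h of the day,
as a set rather than a contiguous window. Each arm's mean magnitude over
that set is its session acceleration value, and the asymmetry index
`(right − left)/(right + left)` of those means identifies the weaker side
by sign. Cohort analysis is descriptive (medians, type-7 quartiles),
longitudinal (per-patient T2 − T1 deltas), and correlational: Spearman's
rank correlation (mid-ranks on ties) of the affected arm's acceleration
against each score at T1, at T2, and for the deltas — nine cells, no
multiple-testing correction.

## Tunable parameters

| Key | Default | Units | Why |
|---|---|---|---|
| `filter.order` | 5 | – | steep roll-off below 3 Hz |
| `filter.cutoff_hz` | 3 | Hz | separates posture/gravity from movement |
| `filter.zero_phase` | `FALSE` | – | causal single pass; forward–backward optional |
| `decimate.window` / `stride` | 96 / 48 | samples | 3 s mean, 50 % overlap, 0.67 Hz output |
| `transient_exclude_s` | 2 | s | zero-state filter warm-up kept out of selection |
| `sync.max_lag_s` | 90 | s | power-on offsets are seconds-scale |
| `trim.eps_ms2` | 0.01 | m/s² | idle threshold on the decimated series |
| `trim.min_run_s` | 300 | s | don't trim brief stillness |
| `session.min_overlap_h` | 2 | h | less gives unstable activity deciles |
| `activity fraction` | 0.10 | – | the most-active-decile definition |

Two interpretive choices deserve a note. The alignment objective is the
*mean* absolute difference, not the raw sum: a sum over a varying-length
overlap is trivially minimized by the shortest overlap, and an unsigned
difference is required for a meaningful minimum. And the selected "most
active period" is a set of sample pairs, not a contiguous window — the
selection rule is defined on sample pairs, and a contiguous-window variant
would be a different (out of scope) statistic.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions the pipeline assumes: a
default of 18 patients, each with 24 h bilateral recordings at T1 and T2.
Per patient a latent motor ability `u ∈ [0, 1]` is drawn uniformly on
\[0.05, 0.9\] at T1 and shifted by a Gaussian improvement
(mean 0.12, sd 0.08, clipped) at T2. Each session consists of:

* a slowly re-orienting unit-gravity vector per wrist (sinusoidal angle
  wander below 0.2 Hz) — removed by the high-pass filter;
* activity bouts on a shared left/right schedule (bimanual daily
  activity): Poisson 20/h while awake (an 8 h sleep block has none),
  duration 30 ± 12 s, band-limited oscillation at 3–10 Hz with amplitude
  2.0 ± 0.8 m/s², modulated within each bout by a piecewise-linear random
  envelope with ~3 s knots — daily movement intensity fluctuates on a
  seconds scale, and that shared fine structure is also what makes the two
  arms alignable;
* the affected arm's bout amplitude multiplied by the monotone deficit
  link `0.15 + 0.85 u` (severely affected arms still get carried along in
  bimanual movement, hence the non-zero floor);
* a per-patient lognormal overall-activity factor (sdlog 0.15): patients
  differ in how active a day they record, independent of deficit;
* white sensor noise (sd 1.5 counts), 8-bit quantization with saturation;
* a start-time offset of the right device drawn from ±15 s, and trailing
  gravity-only idle stretches per arm.

Clinical scores are noisy monotone readouts of `u`: MAS is
`round(15·clip(u + ε))`, MAL subscales are `5·clip(u + ε′)` on the 1/30
grid, with `ε` Gaussian (sd 0.05) and rounding half-away-from-zero (so
`u = 0.5` with zero noise gives MAS 8, MAL 2.5).

The oscillation band is placed at 3–10 Hz deliberately: the pipeline's
high-pass removes everything below 3 Hz, so synthetic "activity" must live
above the cutoff to be visible — as real dynamic arm movement is. Users
should expect sub-3 Hz synthetic movement to vanish from the output.

**What the generator does not emulate**: compensatory movement patterns and
learned non-use (activity that the deficit link cannot represent),
inter-day behavioral variability between T1 and T2 beyond the latent
improvement, heteroscedastic sensor noise, clock *drift* (only a constant
offset), and any claim of distributional fidelity to a real cohort's
acceleration values — defaults merely land the per-arm means in a
plausible 0.5–3 m/s² range. Tests passing on synthetic cohorts therefore
validate the pipeline's mechanics and statistical behavior, not clinical
conclusions about real patients.

## Numerical and degenerate-input choices

* Filtering is causal from zero initial state; the first 2 s of each
  recording are flagged transient and excluded from the activity candidate
  pool (both arms), avoiding start-up spikes in the selection.
* Lag ties are broken toward the smallest |lag|, then the negative one;
  top-decile ties at the threshold toward the earlier timestamp — both
  make results permutation-stable and reruns byte-identical.
* An all-idle series raises an error rather than returning an empty
  session; a session whose common support falls below the configured
  minimum is rejected, and the pipeline excludes that patient wholly
  (partial patients would distort the longitudinal contrasts) while
  recording the reason in the manifest.
* Spearman p-values: exact permutation enumeration for n ≤ 9, the
  t-approximation `t = ρ√((n−2)/(1−ρ²))` above. At the cohort sizes this
  package targets (n = 18) the t-approximation's type-I error is verified
  by simulation in the test suite.
* The asymmetry index of an all-zero selected set is defined as 0.

## Problem sizes used in the test suite

The study conditions are 24 h recordings, but the validation suite scales
durations down so that the full battery runs in minutes on one core:
round-trip and unit tests use seconds-to-minutes recordings; sync-offset
recovery uses twenty 2 h sessions; side-of-weakness recovery uses two
hundred 0.25 h sessions (with proportionally shortened idle tails and a
±30 s lag search); the coupling check correlates affected-arm acceleration
with MAS on twenty cohorts of 50 patients at 0.5 h per session; the null
check uses 2000 replicates at n = 18. Short sessions carry more
bout-sampling noise than a 24 h day, so cohort-level correlations measured
at these sizes are conservative relative to the generator's day-scale
behavior.

## Known limitations

* A constant lag is the only clock correction; real devices can also
  drift, which a single offset cannot absorb over 24 h.
* The idle trimmer needs thresholds (`eps`, `min_run_s`); very quiet real
  wear time below 0.01 m/s² for over 5 min would be trimmed if it ends the
  recording.
* The top-decile statistic is sensitive to how much of the candidate pool
  is genuine activity; for very short recordings the decile mixes in floor
  noise, which is why the package enforces a minimum overlap.
* MAL is self-reported; the generator models it as a noisy readout of the
  same latent ability as MAS, which is a simplification of how self-report
  diverges from capacity.
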