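---
title: "Quantifying chronic pain from pulse and temperature recordings: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chronic pain from pulse and temperature recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The measurement problem

Chronic pain is assessed almost exclusively by subjective self-report on a
0–10 scale. A low-cost, electrode-free home device that records
photoplethysmogram (PPG) pulse waveforms at three sites (temple, carotid,
pointer finger) and skin temperature at five sites (forehead, temple, wrist
top, wrist bottom, finger), all sampled at 66.67 Hz, makes it possible to
ask whether autonomic physiology carries a usable pain signal. Each
ten-minute session is bracketed by two self-reported scores (start and
end); the analysis question is how well physiological features predict
those scores, both within a subject and pooled across subjects.

`painmeter` implements the full analysis chain — artifact-robust pulse
preprocessing, height-invariant feature extraction, per-subject and pooled
regression, and an evaluation harness — together with a synthetic cohort
generator with a known pain-to-physiology coupling, so every stage can be
validated against ground truth. No real recordings ship with the package;
all cohorts here are synthetic and labeled as such.

## Preprocessing: peaks, stability, windows

Subject motion corrupts the pulse channels, so the time axis is filtered
before any feature is computed.

**Peak detection.** A 100-sample window S1 (≈1.5 s) slides one sample at a
time. With `m` the mean of S1 and S2 the last 20 samples (≈0.3 s) of S1, a
peak is declared when S2's first and last values are below `m` and S2's
maximum exceeds `m`; the peak is the index of that maximum. Overlapping
windows re-detect the same apex, so detections within 0.25 s are merged to
the largest-amplitude index (earliest on ties). The 0.25-s radius is below
half the shortest physiological inter-beat interval accepted later
(0.6 s), so distinct beats cannot be merged. The slide step (1 sample) and
the merge rule are this package's choices where the rule itself fixes
neither; both are covered by a brute-force oracle test that evaluates the
window predicate at every offset.

**Stability.** Every run of 6 consecutive peaks is tested on its 5
inter-peak intervals `I`: mean `I_ave` in 0.6–1.2 s, population SD
`d < 0.2` s, and every `I` within 0.9–1.1 × `I_ave`. Runs advance one peak
at a time; a sample is stable iff covered by at least one fully stable run,
whose extent is `[first peak, last peak)`. Tails without pulse evidence are
unstable. Interpreting `d` in seconds, the population-SD convention, the
one-peak advance, and the run-extent rule are documented package decisions;
the thresholds themselves are the standard values for this detector.

**Windows.** The stable spans — intersected across every sensor in the
active combination, since a window is usable only when all requested
channels are stable — are tiled left-to-right with contiguous 10-s windows;
remainders are discarded and windows never straddle a gap. Sample counts
therefore shrink monotonically as sensors are added to a combination (this
is provable from the floor function and is also tested).

All coordinates are 1-based sample indices with half-open `[start, end)`
spans, converted to seconds through the per-recording sampling rate.

## Features and labels

Within each window, pulses are segmented by the minimum strictly between
adjacent peaks (earliest index on ties); the first and last partial pulses
are dropped. Per pulse: rise width `L_R` (valley→peak), fall width `L_F`
(peak→valley); between pulses: `PPI_H` (peak→peak) and `PPI_L`
(valley→valley). Only width parameters are used because pulse *height*
depends on how tightly the device is worn; every feature is invariant to
positive affine amplitude transforms, and the tests assert this bitwise at
the index level. Per window and sensor the mean and population SD of each
parameter are taken — the SD of `PPI_H` is the pulse-rate-variability
feature — plus the five temperature means and four derived features:
temple/finger and forehead/finger ratios and differences. Window
temperature SDs exist behind an opt-in flag but are off by default: the
feature list is defined by the more specific prose enumeration (means
only), and the flag preserves the alternative reading.

Each window inherits the recording's start score if its midpoint falls
before the recording midpoint, else the end score (a midpoint exactly at
half duration counts as second half — the half-open convention). This
half-split labeling is an approximation on real data, since nobody knows
when pain actually changed; the synthetic generator switches latent pain
exactly at the midpoint so that, in synthesis, the approximation is exact
and downstream machinery can be validated in isolation.

All features are z-scored. Unlike a single global pre-pass, the center and
scale are refit on the training fold of every cross-validation split and
applied to the held-out fold: a global pass would leak held-out statistics
into training. Zero-variance training features are dropped per fold.

## Models

*Individual level.* Per subject, recursive feature elimination with a
linear base model: fit least squares on the standardized current set, rank
by absolute standardized coefficient, remove exactly one least-important
feature (ties: the latest in canonical column order is removed, so the
earlier duplicate survives; aliased or constant columns rank lowest), and
repeat down to 5 features, then fit the final linear model. The importance
metric and one-at-a-time removal are the canonical linear-model choices,
made here explicitly because the procedure's description fixes neither.

*Population level.* Pooled across subjects, a random-forest regression
(`ranger` backend): trees grown on bootstrap samples with a random feature
subset per split, prediction = mean over trees, hence always inside the
training label range. Defaults are 500 trees, per-split feature fraction
1/3, bootstrap on, fixed seed; all exposed in the model spec. The
simulation studies below use smaller forests (documented per study) since
their conclusions do not depend on forest size.

Every non-empty subset of the three pulse sensors (7 combinations, ordered
by size then sensor code) can be run; per-subject results report the best
combination by cross-validated r, which is optimistic and labeled
"combination-selected".

## Evaluation

Leave-one-recording-out cross-validation (LORO): all windows of one
recording are held out together, normalization and model are refit on the
rest. Metrics over windows: Pearson r, RMSE (pain-score units), ICC(3,1) —
the Shrout–Fleiss two-way mixed, single-measure, *consistency* coefficient
with windows as targets and {reported, predicted} as the two raters,
computed from the ANOVA mean squares and cross-checked in tests against an
independent `aov()` oracle — and Bland–Altman bias ± 1.96 SD limits, with
the reported score (the reference measurement) on the x-axis. Metrics are
computed over windows, the granularity per-window scatter reporting
implies; the returned predictions table carries recording identifiers, so
recording-mean variants are one `aggregate()` away for callers who want
them.

**Permutation null.** The exchangeable unit is the recording: each
recording's (start, end) score pair is moved *as a pair* to a random
recording, preserving within-recording score structure, and the full LORO
pipeline is refit per permutation; the statistic is the cross-validated r.
`p = (1 + #{null ≥ observed}) / (n_perm + 1)` (add-one smoothing, so p is
never 0 and the smallest attainable p with 200 permutations is 1/201 ≈
0.005).

## The synthetic generator

The generator's purpose is *timing fidelity with known truth*, not optical
realism. Design choices:

- **Beat shape.** Each beat rises over `rise_fraction` of its interval and
  falls over the remainder, as two raised-cosine arcs taken to a
  `sharpness` power (default 8). The sharpening is required, not
  cosmetic: a plain half-cosine beat is above its own window mean for
  longer than the detector's 0.3-s comparison window at physiological beat
  intervals, so the detector predicate could never fire. A 2% unsharpened
  arc is mixed in so the waveform decreases strictly toward the beat onset
  at sample resolution (the pure sharpened arc underflows to the baseline
  near the valley, which would leave a tie region and bias the detected
  valley early by about two samples). Valley and apex positions — the only
  things features depend on — are preserved exactly, so with zero noise the
  extracted `L_R` equals `rise_fraction × IBI` and mean `PPI_H` equals the
  base IBI to within two sample ticks (asserted in the acceptance tests).
- **Coupling defaults.** Slopes per unit pain: IBI −0.012 s (pain raises
  heart rate; the negative sign also keeps pain-10 IBIs ≈ 0.73 s, well
  inside the 0.6–1.2 s stability band), IBI jitter SD +0.0015 s,
  rise fraction +0.008, finger temperature −0.12 °C (peripheral
  vasoconstriction), small negative slopes at the other sites. No effect
  sizes exist to copy — on real subjects even the directions were
  inconsistent — so these are free parameters fixed once at values a
  physiologist would call a strong-but-plausible autonomic response; they
  are the package's study conditions, not fitted quantities.
- **Subjects and scores.** Per-subject random effects on baseline IBI
  (SD 0.04 s) and temperatures (SD 0.3 °C). Pain score pairs default to a
  per-subject truncated discretized Gaussian (subject mean uniform in
  2–8, SD 2; end score = start + N(0,1) rounded), reproducing the
  imbalanced coverage of scale endpoints seen in home recordings. An
  `iid` process (uniform 0–10, independent across recordings) and a
  `fixed` process exist for calibration and degenerate-case tests.
- **Temperatures.** Site baselines near 33 °C (forehead) to 30 °C
  (finger) keep the ratio features near 1, plus a slow sinusoidal drift
  and white noise.
- **Artifacts.** A configurable fraction of each pulse channel,
  independently per channel, is corrupted by noise bursts (no
  quasi-periodic peaks), dropouts (flat), or irregular beat trains
  (intervals far outside 0.9–1.1 × any local mean) — each mode designed to
  violate a specific stability rule.

Not emulated: PPG optics (perfusion, motion-coupled baseline wander
outside artifact spans), breathing-band modulation (absent from the
device's filtered output), and any pain dynamics *within* a half-recording.
Passing tests on this generator therefore show the pipeline recovers
timing- and temperature-coded signal under the generator's assumptions;
they cannot show that real chronic pain is so coded — that is what the
device exists to test.

## Simulation studies and problem sizes

Two cohort-scale studies run in the test suite and the acceptance script;
their sizes are chosen so the whole suite runs comfortably on one CPU, and
are stated here as the package's own study design:

- **Null calibration.** 50 replicate zero-coupling cohorts (4 subjects × 6
  recordings × 120 s), scores drawn i.i.d. across recordings, 200
  permutations each; the empirical rejection rate at α = 0.05 must fall in
  the exact binomial 95% band [0.013, 0.134]. Scores are i.i.d. here
  because the permutation's exchangeable unit is the recording:
  subject-clustered scores combined with subject-signature features
  violate recording-level exchangeability and make the test
  anti-conservative — a limitation shared by any recording-level shuffle
  on subject-clustered data, and worth remembering when interpreting real
  cohorts. The forests in this study are deliberately tiny (8 trees,
  depth 4): permutation calibration is model-agnostic, so model quality
  only shifts power, never size.
- **Parameter recovery.** One default-coupling cohort of 12 subjects × 4
  recordings × 150 s. The single-sensor population model must reach
  cross-validated r ≥ 0.6 with permutation p ≤ 0.01 at 200 permutations
  (30 trees, depth 7), and at least half of the 12 combination-selected
  individual models must reach r ≥ 0.49. These thresholds are synthetic
  design targets mirroring the qualitative field result (a moderately
  predictive population model, individual models good for a subset of
  subjects); they are not reproductions of any human-subject value.

## Numerical conventions and degenerate inputs

- Population SD (divide by n) throughout preprocessing and feature
  aggregation; sample SD in z-scoring and Bland–Altman limits (the
  standard conventions of each context).
- Ties: valley ties to the earliest index; peak-merge ties to the earliest
  max-amplitude index; RFE importance ties remove the latest canonical
  name; a window midpoint exactly at half duration is second-half.
- Fewer than 6 peaks → the whole recording is unstable (warning). Fewer
  than 2 complete pulses on any active sensor → the window is dropped and
  counted. Constant labels → individual model refuses; constant
  predictions or observations → correlation refuses rather than returning
  NaN. Zero mean finger temperature → ratio features are flagged NA.
- All stochastic stages take explicit integer seeds; per-recording
  sub-seeds are derived deterministically from the master seed, so cohorts
  are reproducible element-wise and recordings are independent given
  distinct sub-seeds.

## Known limitations

- The half-recording label assignment is exact only in synthesis; on real
  data it mislabels windows whenever pain changed away from the midpoint.
- Combination selection on cross-validated performance (individual level)
  is optimistic; an honest estimate would nest the selection inside
  another CV layer.
- The permutation test assumes recording-level exchangeability (see
  above).
- The generator's common coupling direction across subjects makes the
  population task easier than heterogeneous real physiology; the
  per-subject random effects restore some, not all, of that difficulty.
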