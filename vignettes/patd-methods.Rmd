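---
title: "patd: methods, conventions and the synthetic signal model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{patd: methods, conventions and the synthetic signal model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents how `patd` turns raw wearable recordings into
activity-type classifications: the data model, the segmentation and
feature conventions (including every tie-break and degenerate-input rule),
the model and evaluation designs, and the synthetic signal generator with
the rationale for each default parameter. Nothing here is required to use
the package — it is the reference for anyone auditing results or
replacing a stage.

## 1. Data model

A `subject_record` holds, for one person:

* five `acc_stream`s — tri-axial acceleration in g at nominal 50 Hz, one
  per body position (`chest`, `left_hip`, `right_hip`, `left_pocket`,
  `right_knee`), each with its own clock column `t` in seconds;
* one `gps_stream` — fixes at nominal 1 Hz with latitude/longitude in
  degrees and elevation in meters;
* a `label_track` — half-open intervals `[t_start, t_end)` labeled with
  one of six activities (`lying`, `sitting`, `standing`, `walking`,
  `nonlevel_walking`, `running`) and a protocol (`semi_structured` or
  `real_life`);
* the cohort (`young` or `old`).

Constructors validate monotone timestamps (duplicates keep the first
occurrence with a warning; non-monotone input is an error), finite values,
coordinate ranges, non-overlapping label intervals, and a median sampling
interval within 10% of nominal. On-disk layout is one directory per
subject with `acc_<position>.csv` (`t,ax,ay,az`), `gps.csv`
(`t,lat,lon,elev`), `labels.csv` (`t_start,t_end,activity,protocol`) and
`meta.json`; numbers are written with 17 significant digits so a
write/read/write cycle is byte-identical.

## 2. Segmentation

| parameter       | default | meaning |
|-----------------|---------|---------|
| `window_len_s`  | 2       | window length, seconds |
| `step_s`        | 1       | step between window starts (50% overlap) |
| `purity_min`    | 0.8     | minimum fraction of the window covered by one label |
| `min_fill_frac` | 0.8     | minimum fraction of expected samples present |

Windows are half-open `[t, t + 2)` on the subject clock. A window is kept
only if (a) at least 80% of the expected `fs * window_len` samples are
present (sensor dropouts suppress windows rather than biasing features)
and (b) a single activity label covers at least 80% of the window span;
otherwise the window is unlabeled and excluded. Label purity is computed
from interval overlap, so windows spanning an activity transition drop
out. GPS fixes are attached to each window by the same half-open rule.

## 3. Accelerometer features (85 per window)

All features are computed per window on the raw samples (no detrending,
no filtering). Signals: the three axes `x, y, z` and the total
acceleration `sqrt(x^2 + y^2 + z^2)`.

Time domain (60):

* mean, standard deviation (n−1 denominator), range — each of the four
  signals (12);
* pairwise axis correlations xy, xz, yz (3); a zero-variance axis yields
  correlation 0;
* kurtosis, skewness, average absolute deviation from the mean — per axis
  (9), population-moment definitions; both moments are defined as 0 for a
  zero-variance signal;
* 10-bin histogram counts per axis (30): bins equally partition
  `[min, max]`, right edge closed in the last bin; a constant signal puts
  all samples in bin 1;
* dominant peak interval and peak count per axis (6): peaks are strict
  local maxima with prominence ≥ 0.05 g (walk-out-to-higher-ground bases,
  greedy by descending height) and minimum separation 0.2 s; the interval
  is the mean gap between consecutive accepted peaks (0 with fewer than
  two peaks).

Frequency domain (25): for each of the four signals, the one-sided
magnitude spectrum `|X_k| / n` of the raw (unwindowed, non-padded) block
with the DC term excluded gives

* spectral energy (sum of squared amplitudes divided by the number of
  non-DC bins),
* mean dominant frequency and the three largest amplitudes (ties broken
  toward the lower frequency),
* power spectral density (energy scaled by `n / fs`),

which with one extra dominant-frequency statistic for the total signal
makes 25. If the largest spectral amplitude does not exceed
`1e-12 * mean(|signal|)` the spectrum is considered zero up to FFT
rounding and all spectral features are 0 (a constant block has no
dominant frequency).

The exact ordering of the 85 names is fixed by `acc_feature_names()` and
is part of the package contract; the test suite checks every feature
against independent naive-loop and direct-DFT oracles at 1e-9 relative
tolerance.

## 4. GPS features (2 per window)

* `gps_avg_speed` = (sum of consecutive haversine distances) /
  (`t_last − t_first`), haversine on a 6,371,000 m sphere;
* `gps_elev_diff` = `elev_last − elev_first`, signed, so uphill and
  downhill non-level walking differ in sign but not magnitude.

A window with fewer than 2 fixes is invalid; in `acc_gps` mode such rows
are dropped from the feature table (the count is recorded in the
`gps_dropped` attribute), in `acc` mode they are kept.

## 5. Models

`model_config()` fixes the sensor mode (`acc` or `acc_gps`), the scope
(`general` or `individual:<position>`), the number of trees (default
500), the `mtry` rule (`floor(sqrt(p))`) and the seed. Individual-scope
tables have 85 (+2) feature columns; general-scope tables align the five
positions on window start time and concatenate their features under
position-prefixed names, 425 (+2) columns — a window enters the general
table only when all five positions produced a labeled window at that
start. Random forests are `ranger` with `num.threads = 1`, and the seed
is passed to both training and prediction (prediction otherwise draws a
tie-breaking seed from the global RNG, which would break run-level
determinism). Models can be saved/loaded with a version gate.

## 6. Evaluation designs

A cell is a (scenario, age design) pair. Scenarios select protocols:

| scenario | train protocols | test protocol |
|----------|-----------------|---------------|
| S1A | semi-structured + real-life | real-life |
| S1B | semi-structured + real-life | semi-structured |
| S2A | semi-structured | semi-structured |
| S2B | real-life | real-life |
| S3A | semi-structured | real-life |

Age designs select cohorts: `within_old` and `within_young` train and
test inside one cohort; `y_trained_btw` trains on young only and tests on
old; `yando_trained_btw` trains on young plus old and tests on old.
Evaluation is leave-one-subject-out over the *test* cohort: each fold
removes the held-out subject from the training windows entirely, trains
on the training cohorts/protocols, and predicts the held-out subject's
test-protocol windows. Reports pool the confusion matrix across folds
(micro averaging, percentages) and carry per-fold subject lists so leakage
is mechanically checkable. `run_matrix()` executes the full
scenario × design × mode × scope grid deterministically, skipping
infeasible cells with a logged reason, and writes `summary.csv` plus
line-JSON logs; two runs with the same seed are byte-identical.

## 7. Synthetic signal model

Postures produce a placement- and posture-specific gravity direction plus
Gaussian sensor noise (0.03 g; standing 1.3×, as quiet standing shows
slightly more sway than lying/sitting). Locomotion adds, along the
gravity axis, a three-harmonic series at a per-block fundamental, plus a
weaker lateral sway at 0.30× the first harmonic, and motion-induced noise
proportional to the placement's movement amplitude. GPS is synthesized
locally planar (meters, then converted to degrees on the same sphere the
haversine uses) at the drawn speed with per-fix noise of 0.05 m
horizontal and 0.01 m elevation (idealized, barometric-grade); non-level
walking adds a linear elevation trend of `speed × grade` with random
sign.

### Default gait parameters

| cohort | activity | fund. (Hz) | harmonic amps (g) | noise (g) | speed (m/s) | grade |
|--------|----------|-----------|-------------------|-----------|-------------|-------|
| young | walking | 1.90 ± 0.10 | 0.40, 0.18, 0.08 | 0.05 | 1.40 ± 0.10 | — |
| young | non-level | 1.83 ± 0.10 | 0.38, 0.17, 0.08 | 0.05 | 1.20 ± 0.10 | 0.12 ± 0.02 |
| young | running | 2.80 ± 0.15 | 0.90, 0.48, 0.23 | 0.14 | 3.00 ± 0.25 | — |
| old | walking | 1.65 ± 0.10 | 0.33, 0.15, 0.07 | 0.05 | 1.10 ± 0.10 | — |
| old | non-level | 1.59 ± 0.10 | 0.31, 0.14, 0.07 | 0.05 | 0.95 ± 0.10 | 0.12 ± 0.02 |
| old | running | 1.72 ± 0.13 | 0.34, 0.165, 0.078 | 0.065 | 1.20 ± 0.20 | — |

Rationale:

* **Old running near old walking.** The old cohort's running fundamental
  (1.72 ± 0.13 Hz) and speed (1.20 ± 0.20 m/s) sit inside its walking
  distributions (1.65 ± 0.10 Hz, 1.10 ± 0.10 m/s), while the young
  cohort's running (2.80 Hz, 3.00 m/s) is cleanly separated. Running
  retains a universal signature — higher impact noise and a higher
  second-harmonic ratio — so combined-cohort training can still transfer;
  but within the old cohort, running/walking confusion is structural.
  `interval_overlap` quantifies the contrast and the test suite asserts
  the ordering.
* **Non-level vs level walking.** The cadence gap (~3.5%) is below the
  0.5 Hz resolution of a 2 s FFT, so the distinction rests chiefly on the
  GPS elevation trend (and secondarily speed); this is what makes the GPS
  features load-bearing for exactly these two classes.
* **Real-life variance inflation** multiplies noise and block-level
  jitter during real-life sessions: 2.0 (young) vs 1.2 (old), making the
  young cohort's free-living data relatively noisier.

### Placement transforms

| placement | amp multiplier | gain exponent γ | posture geometry |
|-----------|----------------|-----------------|------------------|
| chest | 0.6 | 0.6 | sit/stand 5° apart (unresolvable under 10° session jitter); lying distinct |
| left/right hip | 0.9 | 0.9 | sit/stand 15°; lying distinct |
| left pocket | 1.1 | 1.2 | sit/stand strong; lying only 10° from sitting; extra ≤30° random rotation per session |
| right knee | 1.6 | 2.0 | sit/stand strong; lying 15° from sitting |

Locomotor amplitudes are transformed per placement as
`0.4 * (amps / 0.4)^γ * multiplier`, with the per-subject amplitude
factor applied outside the exponent: distal, leg-borne placements amplify
the *cohort-level* relative amplitude differences between gaits (knee
most), the trunk compresses them, and subject idiosyncrasy is not
amplified along the way. Motion-induced noise scales with the same
multiplier, so the noise cue that separates running is placement-scaled
consistently. The posture geometries are deliberately complementary: no
single placement resolves every posture pair, so multi-placement fusion
has a real advantage, while the knee's combination of strong gait
contrast and nearly clean postures makes it the strongest single
placement overall.

### Between-subject variation

Each subject draws, independently per activity: fundamental offset
(sd 0.08 Hz), speed offset (sd 0.08 m/s), log-normal amplitude factor
(sd 0.10), a log-normal noise factor shared across activities (sd 0.10),
and a per-session device orientation jitter (sd 10°). Independence per
activity matters: drawing one gait factor per subject would freeze each
subject's running/walking gap and remove cross-subject confusion from
leave-one-subject-out folds.

### Schedules and determinism

The default semi-structured session is 8 blocks / 310 s covering all six
activities; the real-life session is 7 blocks / 260 s; sessions are
separated by a 10 s gap and share one subject clock, with all five
placements generated from the same block-level parameter draw (one body,
five devices) and GPS taken once per subject. `generate_cohort()` is
bit-reproducible given a seed and restores the caller's RNG state.

## 8. Problem sizes and runtime

On one CPU: generating and featurizing one default subject takes roughly
5–6 s (5 positions × ~570 s × 50 Hz); a 20-subject-per-cohort pair about
4 minutes. A general-scope leave-one-subject-out design on 20 subjects
(100 trees) runs in tens of seconds. The acceptance script
(`scripts/acceptance.R`) and the heavy test file each complete in 15–20
minutes.

## 9. Limitations

* The generator is a stylized harmonic-plus-noise model: no gait cycle
  asymmetry, double-support timing, turning, or terrain texture; GPS has
  no multipath, dropouts or urban-canyon bias, and elevation noise is
  idealized (0.01 m) rather than GNSS-grade.
* Within-cohort parameter distributions are unimodal; real populations
  mix gait styles.
* Only the six listed activities and five placements are modeled;
  transitions between activities are excluded by the purity rule rather
  than classified.
* Absolute accuracies on synthetic data are not estimates of field
  performance; the package's claims are about orderings and contrasts
  (cohort confusion asymmetry, GPS contribution, fusion vs single
  placement, transfer designs), which the test suite checks directly.
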