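---
title: "Estimating work hours from passive smartphone sensing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating work hours from passive smartphone sensing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(workmode)
library(dplyr)
```

## The problem

Work hours are conventionally equated with presence at the worksite. For
people with flexible schedules that equation breaks in both directions: a
lunch break spent at the hospital is not work, and an evening spent answering
work messages from the sofa is. `workmode` implements a two-part answer:

1. **GPS-defined work hours.** A fix within 1 km of a registered workplace
   (up to five per participant), sustained for a continuous 1800-second
   confirmation period, switches work-hour recording on; a sustained
   1800-second absence switches it off. GPS is sampled every 600 seconds to
   save battery.
2. **Probability in work mode.** Human–smartphone interaction differs between
   working and non-working states: which apps notify, whether and how fast
   the user reacts, and how long the ensuing usage episode lasts. A
   per-participant classifier converts these patterns into a per-minute
   probability of being in work mode.

Crossing the two signals at a 0.5 threshold segments every day into four
states: **office working** (at the worksite, probability > 0.5), **break at
the worksite** (at the worksite, probability ≤ 0.5), **off work**, and
**remote working** (off-site, probability > 0.5). A probability of exactly
0.5 falls on the non-working side, since only probabilities *higher* than
0.5 are read as on-working.

## Features: mental chronometry on screen events

The event log contains screen-on/off timestamps at 1-second resolution, the
label of the active app, and notification timestamps. Notifications act as
stimuli, screen events as responses. Within each 1800-second window the
stream is summarised into **five features per app**:

| feature | meaning |
|---|---|
| `f1` usage duration (s) | summed app usage clipped to the window |
| `f2` notifications inside episodes | arrivals while that app is in use |
| `f3` notifications outside episodes | arrivals while it is not |
| `f4` reaction time (s) | delay from the triggering notification to the start of the usage episode |
| `f5` reaction intensity (s) | duration of the notification-triggered episode |

The feature vector has length 5 × (number of apps in the participant's
vocabulary). `f4`/`f5` are missing when no notification-triggered episode
starts in the window; missing values are imputed by resampling observed
values, with the resampling pool fitted on training folds only.

Two conventions deserve explicit statement because the definitions above do
not fully determine them:

* **Notification–episode pairing.** An episode is *notification-triggered*
  when at least one same-app notification arrives after the previous episode
  of that app ended and before this one started. The episode absorbs all such
  notifications and the reaction time is measured from the most recent one.
  This reproduces the canonical worked examples: a phone call answered one
  second later gives `f4 = 1 s`, `f5 = 900 s`; two evening notifications at
  20:00:00 and 20:10:00 followed by a 15-minute video session starting at
  20:10:05 give `(f1..f5) = (900, 0, 2, 5, 900)`.
* **Window aggregation.** `f4`/`f5` are arithmetic means over the pairs whose
  episode starts inside the window.

### Exclusion rules

Training windows are aligned at an 1800-second stride from local midnight.
A window is dropped when it overlaps the nightly exclusion span
(midnight–05:45, when non-use would be confounded with sleep), when it mixes
GPS-defined on- and off-working minutes, or when its day recorded no screen
event at all. Only **typical workdays** — off-working at both ends of the
day, starting before noon, with more than four hours of total work — are
used for training, and a participant needs at least five of them.

## The two-stage model

**Stage 1** is a per-participant gradient-boosted-tree classifier
(`xgboost`) on the window features, with binary log-loss and two-class
probability output. Cross-validation is 5-fold; folds are blocked by day
(all windows of one day share a fold) and balanced by label prevalence, so
temporally adjacent windows never straddle a fold boundary. Boosting
hyperparameters are not dictated by the method and default to depth 4,
learning rate 0.1, up to 400 rounds with early stopping on the held-out
fold; the refit model uses the median of the fold-optimal round counts.

**The window-to-minute bridge.** The classifier is trained on 1800-second
windows but the final output is per-minute. For every minute *t* of the
evaluated span (05:45–24:00) the 1800-second window *ending* at *t* is
featurised and scored, giving a provisional per-minute series.

**Stage 2** smooths that series with a small 1-D convolutional network: the
input is the lookback window of the `L = 60` preceding provisional
probabilities, the target the GPS state of minute *t*. The architecture is
three convolution layers (ReLU; max pooling after the first two, global
average pooling after the third) followed by two fully connected layers
(ReLU, then one sigmoid unit), trained with Adam on binary cross-entropy.
To avoid leakage, stage-2 training inputs are *out-of-fold* stage-1
probabilities: each training day is scored by the fold model that never saw
it. Sequences never cross midnight, and the first `L` minutes of each day
pass the provisional value through unchanged (the warm-up rule).

The network is implemented directly in vectorised R (im2col plus BLAS
matrix products), with gradients verified against numerical differentiation
in the test suite. Sizing is a package choice: filter counts 8/16/16,
kernels 5/5/3, hidden width 16, learning rate 2e-3, at most 30 epochs with
early stopping (patience 5) on a 10% validation split, and training pairs
subsampled at a 3-minute stride (inference stays at 1-minute resolution).
The task — monotone temporal smoothing of a single probability channel —
needs little capacity, so the network is kept small (under 2000 parameters)
to train per participant in seconds on one CPU; all sizes are configurable
through `cnn_config()` when more capacity is wanted.

## Evaluation protocol

* **Transition exclusion.** Minutes within ±15 minutes of a GPS on/off
  switch are excluded from accuracy and ROC computations — the geofence
  itself is only cadence-accurate there, so those labels are unreliable.
* **Per-participant AUC** is rank-based with half credit for ties, computed
  over all unmasked minutes. Holidays pooled with workdays contribute
  negatives; holidays alone have one class and therefore no AUC. An AUC
  below 0.7 is read as low discrimination.
* **Reference baseline.** The "9-to-5" paradigm predicts work from 09:00 to
  17:00 on every day. On the 1095-minute evaluated span an all-off holiday
  yields exactly 615/1095 ≈ 0.562. The baseline is evaluated without the
  transition mask (it does not depend on the geofence); this is a
  documented choice.
* **Paired t tests** (two-sided, closed form) compare algorithm and
  reference accuracies per person-day; the stage-2 gain over stage 1 is
  tested one-sided across participants.
* The **greedy feature search** ranks features by gain importance and grows
  the subset until the cross-validated AUC is within 0.01 of the
  full-feature AUC; the **stability analysis** refits the whole pipeline on
  growing day prefixes against a fixed held-out set.

## What the synthetic cohort emulates — and what it does not

No public data accompany the method, so the package ships a generator whose
output exercises every pipeline stage with known ground truth:

* Per-minute schedules: work start drawn around 08:45 (truncated before
  noon), duration around 9 h, Poisson(1.5) breaks of ~35 min, Poisson(1)
  evening remote episodes of ~50 min, holidays with probability 0.25 —
  plausible magnitudes for hospital staff, chosen once and documented here;
  they are free parameters, not reproduced from any dataset.
* Behavioural regimes: breaks switch the *response behaviour* to the
  off-work regime while GPS stays at the worksite; remote work is the
  mirror case. Per-app Poisson notification arrivals, Bernoulli responses,
  log-normal reaction times and episode durations all differ between
  regimes. The `contrast` parameter interpolates the off-work regime toward
  the on-work one: at 0 the regimes are identical (a null model used by the
  calibration tests), at 1 they are fully separated (the documented
  high-contrast default).
* Measurement: GPS at a fixed 600-second cadence with isotropic Gaussian
  noise (50 m default) and linear commute interpolation; events at 1-second
  resolution; overlapping candidate episodes are resolved as zero-gap app
  switches; event rates are attenuated ×0.1 during the nightly sleep span.

The generator deliberately omits phone-off periods, multi-device use,
OS-specific logging quirks, indoor positioning error structure, and any
correlation between schedule and behaviour beyond the regime switch. Passing
tests therefore show that the pipeline recovers the states its model class
assumes; they do not certify performance on real cohorts, where stage-1
discrimination is typically weaker and the temporal stage correspondingly
more important.

## Numerical choices and degenerate inputs

* Work intervals are backdated: the 1800-second confirmation is a detection
  latency, so an interval starts at the first fix of the qualifying in-range
  run and ends at the last in-range fix before the qualifying out-of-range
  run. A silent GPS gap longer than the confirmation counts as out of range.
  Intervals are split at local midnight; "more than four hours of work"
  sums interval durations rather than spanning first-to-last.
* All wall-clock rules (noon, 05:45, midnight) are evaluated in the
  participant's local time zone, supplied in the configuration.
* Ties: probability exactly at the threshold → non-working; equal values in
  max pooling keep the earlier position; AUC ties get half credit.
* Degenerate inputs fail loudly: one-class training data, all-missing
  feature columns, fewer than five typical days, lookbacks longer than the
  day span, and misaligned minute grids are errors, not silent repairs.
* Determinism: every stochastic step (simulation, fold assignment,
  imputation, boosting, weight initialisation, batch shuffling) derives from
  an explicit seed; per-participant streams are derived from the global seed
  and the participant id, so cohorts are reproducible participant by
  participant.

## Validation at desk scale

The package validates itself on a synthetic cohort of 20 participants × 30
days (profile seeds 1..20, high-contrast defaults): per-participant models
are trained on the first 21 days and evaluated on the held-out 9 days with
the transition mask. With the shipped defaults this runs in under ten
minutes on one CPU. The test suite asserts the cohort-level outcomes — the
mean held-out AUC, the fraction of participants above the 0.7 floor, and a
positive stage-2 gain — alongside exact oracle equivalences (window features
vs brute-force interval arithmetic, rank AUC vs the all-pairs count,
geofence intervals vs an exhaustive run-scan) and the analytic baseline and
worked-example values quoted above. `scripts/acceptance.R` re-runs the
cohort experiment from scratch and writes the two headline numbers as JSON.

## Known limitations

* The window-to-minute bridge (sliding 1800-second windows at 60-second
  stride) and the stage-2 lookback of 60 minutes are conventions of this
  implementation; the method they operationalise does not pin them down.
* Evaluation uses the GPS-defined state as ground truth, so the reported
  AUCs measure agreement with the geofence, not with true work — that is
  exactly what makes break/remote detection *divergence* rather than error,
  and it is why the transition mask matters.
* Break and remote-work detection over-claims: during long stretches
  without any screen event the feature window is uninformative, the
  probability drifts toward its prior, and hard thresholding at 0.5 turns
  that drift into spurious short break/remote episodes. On synthetic data
  the detected divergence minutes exceed the scheduled ones, so per-minute
  precision is modest even when the majority of scheduled divergence is
  recovered and daily detected divergence tracks the schedule closely. Any
  minute-level overlap statistic between detected and scheduled episodes
  should be read with this in mind.
* Day-blocked cross-validation is stricter than window-level
  cross-validation; window-level folds would inflate stage-1 AUCs through
  temporal leakage.
* Stage 2 sees only the probability sequence (single channel); no recurrent
  or attention-based alternatives are provided.
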