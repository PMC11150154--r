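---
title: "Detecting nocturnal BP surges in seconds: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting nocturnal BP surges in seconds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secsurge)
```

## The problem

Obstructive sleep apnea episodes and sympathetic bursts trigger brief,
acute systolic blood pressure elevations lasting several tens of seconds —
sec-surges. They are invisible to conventional intermittent nocturnal BP
monitoring and far too numerous to screen by hand in an overnight
beat-by-beat recording of 25,000–35,000 beats. `secsurge` implements the
full chain: candidate extraction from the beat-by-beat systolic series,
a 48-feature description of each candidate, supervised learning of a
threshold AND-rule, evaluation against expert labels, and the conventional
and per-surge nocturnal BP variables.

The constraint shaping every design choice is auditability: the classifier
must remain a conjunction of per-feature threshold conditions a physician
can read, not a tree ensemble or a logistic model.

## Candidate extraction

A surge episode is summarized by three landmarks on the valid beats of the
series (artifact- and gap-flagged beats are transparent everywhere):

* **Peak** — a strict local maximum of SBP within a centered sliding time
  window (`window_s`, default 60 s). A time-based window is used because
  beat intervals are irregular. Plateaus yield exactly their earliest
  beat; a constant stretch yields nothing.
* **Start** — the end of stable pre-surge SBP. Walking backward from the
  peak, the start is the latest beat whose trailing window of
  `stability_beats` (10) valid beats spans at most `stability_range_mmHg`
  (5). Two refinements make this robust for smooth surges: the stable
  window must sit more than one stability range *below the peak*
  (otherwise the flat apex of a slow surge, whose trailing window is
  nearly level, would masquerade as baseline), and the returned beat is
  backed down any strictly decreasing run so that a gentle rise is not
  clipped partway up. If no stable window exists within `max_lookback_s`
  (120 s) the minimum-SBP beat in the lookback is used and flagged as a
  fallback.
* **End** — the first valid beat after the peak whose SBP has decayed by
  `decay_fraction` (0.75) of the amplitude (peak SBP − start SBP). If the
  level is never crossed within `max_recovery_s` (180 s), the span
  minimum is used and flagged.

The 0.75 decay fraction defines the end point of the method. The window,
stability, lookback and recovery spans are engineering defaults sized so a
surge of several tens of seconds fits comfortably inside them; all are
exposed in `detector_config()`. Candidates with amplitude below
`min_amplitude_mmHg` (15) are discarded, fallback intervals that swallow a
neighboring candidate's peak are dropped, and residual interval overlaps
are clipped at the previous candidate's end. Recordings are split into
independent segments wherever consecutive valid beats are more than
`gap_split_s` (10 s) apart, so searches never bridge a signal dropout.

## The feature catalogue

Each candidate is described by exactly 48 features in six groups of eight:
*reactivity phase* (rise dynamics: onset slope, jerkiness, acceleration,
25%/75% rise times and their ratio, reversals, pre-start baseline range),
*recovery phase* (the mirrored fall dynamics, with undershoot in place of
baseline range), *amplitude* (level features plus area above the start and
peak-above-night-median context), *upward*, *downward* (duration, slopes,
beat counts, monotonicity, partial areas) and *whole duration* (total
duration, symmetry, segment mean/SD, time above half amplitude). Every
feature is a one-line formula over (start, peak, end) and the SBP beats
between them; `feature_catalogue()` returns the definitive list. Two
covariances are enforced by tests: adding a constant to all SBP values
shifts only level features, and dilating time by *k* multiplies durations
by *k* and divides slopes by *k*. Diastolic values are carried through the
I/O layer but deliberately unused by detection and features.

## Rule learning

Each feature is swept over all distinct observed thresholds in both
directions and scored by the balanced F-measure; ties prefer the smaller
positive region. Within each group only the best feature survives (the
groups encode complementary clinical perspectives, so they are never
duplicated); groups whose best single-feature F falls below
`min_single_feature_f` (0.5) are dropped; at most `max_conditions` (6)
features proceed.

The joint thresholds are then fitted by an exhaustive grid search over the
Cartesian product of per-feature quantile grids (5th–95th percentile).
Two grid choices matter:

* **Resolution.** The default is 13 points per feature, chosen so that a
  full six-condition rule (13^6 ≈ 4.8M combinations) stays within the
  built-in exhaustive-search cap of 10^7 combinations. Quantile rather
  than raw-value spacing makes the grid scale-free.
* **A no-op point.** Each grid additionally contains the feature's most
  permissive observed value (minimum for `≥`, maximum for `≤`), so a
  condition can be inactive. Without it, a percentile-bounded grid forces
  every condition to clip ~5% of the training data, which both costs
  recall and makes a perfect F unattainable on perfectly separable data.

The search is evaluated exactly via k-dimensional cumulative counts over
the grid lattice — algebraically identical to brute-force enumeration (and
tested against an independent brute-force oracle) but linear rather than
multiplicative in the number of candidates. Equal-F ties prefer higher
recall, then the most permissive thresholds in condition order. Thresholds
are inclusive, matching the `X ≥ A` reading of a clinical criterion.

Training candidates are labelled by the *same* matcher used at evaluation
time (peak containment in the label interval ± tolerance), so training and
test semantics coincide.

## Evaluation

Matching is greedy one-to-one in time order: a detection pairs with the
earliest unmatched label whose interval, widened by `tolerance_s` (10 s),
contains the detected peak time. Peak containment is deliberately lenient
about start/end placement, where algorithm and labeller disagree most.
Cross-validation always splits *nights*, never beats, to avoid leakage;
per fold, TP/FP/FN are pooled before computing recall and precision, and
the mean ± SD across folds is reported. Per-night candidate extraction and
feature computation are hoisted out of the fold loop — they depend only on
the series and the detector configuration, which are constant across
folds — so each fold re-runs only selection, grid search and matching.

## The synthetic night generator

`generate_night()` emulates the study conditions the package calibrates
against. Defaults: 7 h of beats at 1.0 ± 0.05 s intervals; baseline
122.2 mmHg with a ± 5 mmHg sinusoidal drift (period 5400 s, random phase);
per-beat noise SD 2 mmHg; per-night surge counts Poisson with means 19.5
(sleep-apnea class) and 16.4 (non-SA); surge amplitudes Normal(26.0, 4.3)
truncated to [15, 60] mmHg; rise times U(10, 40) s and fall times
U(15, 60) s on a raised-cosine template (smooth, unimodal, analytic apex);
30 sub-threshold confuser bumps (amplitude U(5, 12)) per night; 5 artifact
spikes (± 30–80 mmHg over 1–3 beats, flagged). The baseline of 122.2 makes
the mean planted peak 122.2 + 26.0 = 148.2 mmHg. Each SA-class surge is
preceded by one PSG event (apnea/hypopnea/desaturation, duration
U(10, 60) s) ending 10 s before the surge start; placement margins
guarantee no event falls in any *other* surge's association window. The
huge between-patient dispersion of real per-night counts is not modelled
by default (a negative-binomial option exists via
`surge_count_dispersion`); neither are surge bursts, calibration jumps,
tonometry sensor artifacts beyond simple spikes, or diastolic dynamics
(DBP is emitted as SBP − 45 + noise purely so files round-trip).

Annotation landmarks are placed on valid beats, and the annotated peak is
the argmax of the *noise-free* composed signal within the surge span:
noise at a fixed beat has zero mean, so severity calibration stays
unbiased, and noise-free runs recover planted peaks exactly.

What passing tests on this generator shows: the pipeline recovers events
of the documented morphology at realistic noise, confuser and artifact
levels, at the published operating point. What it cannot show: performance
on real tonometry, whose artifact structure, apnea clustering and
patient-to-patient heterogeneity are richer than the model.

## Numerical choices and degenerate inputs

* Times in files are seconds (3 decimals), pressures mmHg (1 decimal);
  internally the algorithms work on beat indices (1-based, as is natural
  in R), avoiding float-equality pitfalls. Annotation times snap to the
  nearest valid beat; a snap above 2 s warns, above 10 s errors.
* Sweep and grid F computations use `F = 2TP/(2TP+FP+FN)`, which is exact
  for TP = 0. Metric conventions: recall = 1 with no labels, precision = 1
  with no detections, F = 0 when both are zero.
* Empty surge classes report `NA` means, never 0.
* Sample (n−1) SD throughout, with a population-SD flag on
  `conventional_variables()`.
* Determinism: every stochastic routine takes an explicit seed and
  restores the caller's RNG state.

## Benchmark sizes

The packaged acceptance analysis uses 20 synthetic nights (~25,000 beats
each, generation seeds 0–19) with 5-fold night-level cross-validation, and
severity calibration over ≥ 200 planted SA-class surges; unit and property
tests use shorter nights (1–4 h) with proportionally reduced event rates
so that surges, confusers and their guard margins still fit.

## Known limitations

Atrial fibrillation and similarly erratic rhythms defeat the stability
criterion and are unsupported. The three-way clinical screening of
detections (sec-surge / undetermined BPV / noisy BPV) is a manual
post-review step: the detector deliberately over-detects subtle BPV rather
than miss surges, and borderline detections should be reviewed before
quantitative analysis. The 48-feature catalogue is this package's concrete
instantiation of the six published group definitions; agreement with other
implementations can only be behavioural (recall/precision on comparable
data), not feature-by-feature.
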