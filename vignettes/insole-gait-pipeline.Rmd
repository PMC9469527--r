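---
title: "Methods: insole gait features and balanced-forest classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: insole gait features and balanced-forest classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and known
limitations behind `insolegait`. It is the reference for every decision
the code makes where the underlying measurement protocol leaves room.

## 1. The measurement model

A subject wears instrumented insoles with seven pressure sensors per
foot (heel, lateral/centre midfoot, lateral/centre/medial forefoot, big
toe), sampled at 100 Hz. The sensors respond between 25 and 550 kPa and
are digitised on a 10-bit scale; below the response floor a sensor reads
zero. Two trials are analysed: a quiet-standing balance test, of which
the last 45 s are used (the first seconds contain a settling transient),
and a walk of two straight 10 m segments.

The sensor coordinates are not part of the device output, so the package
fixes a canonical layout (`sensor_layout()`): heel at the posterior end,
big toe at the anterior end, typical mediolateral offsets, scaled
linearly by insole length (default 250 mm). Centre-of-pressure (COP)
statistics only require a fixed, consistent geometry — absolute
millimetre values depend on this convention and should be compared only
within one layout. The right foot's x-axis is mirrored so that +x points
lateral→medial on both feet, which makes left/right differences
geometrically comparable. Pressure is converted to force with a constant
effective area per sensor (default 1 cm², so 100 kPa ↔ 10 N); any
constant area only rescales force-dimensioned features.

## 2. The synthetic cohort generator

Real recordings of this kind are not publicly available, so the
generator (`generate_cohort()`) emulates the signal structure the
analysis relies on. It is first-class, tested code — the study
conditions, not a convenience fixture.

Per stance, each sensor's pressure curve is a log-normal-shaped bump on
normalised stance time, staggered heel→toe (heel peaks at ~20% of
stance, big toe at ~83%), plus a short contact-load ramp (5 ms on, 20 ms
off) with a sharp heel landing load that decays over the stance. The
per-sample maximum over the seven channels then shows the classic
two-peak (loading / push-off) envelope with a mid-stance valley whose
depth is set by the `peak_valley_ratio_mean` parameter. Signals pass
through the digitisation chain of the device model: optional Gaussian
sensor noise on loaded samples (an unloaded conductive-rubber sensor
reads a clean zero), the 25 kPa deadband, the 550 kPa ceiling, 10-bit
quantisation.

Walking timing: within a segment, strikes alternate between feet; the
opposite foot strikes at `D * (1 - ds/2)` after the current strike,
where `D` is the stance duration and `ds` the double-support fraction.
Each interior stance therefore contains two double-support episodes of
`ds/2` each, so the extracted double-support percentage equals `ds`
(default 20%). Standing sway is a band-limited (≤1 Hz) two-axis
oscillation of a virtual COP mapped back to sensor pressures through a
spatial kernel; its amplitude is set in millimetres.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| `stance_duration_mean` | 0.70 s | typical senior self-paced stance time |
| `stance_duration_between_cv` | 0.08 | moderate between-subject spread |
| `stance_duration_cv` | 0.05 | stride-to-stride variability of healthy gait |
| `peak_valley_ratio_mean` | 1.8 | visually typical two-peak ground-reaction shape |
| `double_support_fraction` | 0.20 | ~10% of stance per episode in senior gait |
| `sensor_noise_sd` | 4 kPa | below 2% of peak pressures |
| `sway_x_mm`, `sway_y_mm` | 5, 8 mm | quiet-standing sway, AP larger than ML |
| `n_steps_per_segment` | 8 | guarantees ≥3 steps/foot after trimming |
| `frail_fraction` | 0.285 | ~29% prevalence in senior community cohorts |
| `faller_fraction` | 0.20 | ~20% 12-month fall recall |

Labels are assigned as deterministic counts (`round(fraction * n)`,
shuffled by seed) so imbalance is exact; the frail and faller labels are
independent unless group effects couple them. `inject_group_effect()`
re-synthesises a labelled group with one generative parameter scaled,
keeping per-subject seeds, which enables parameter-recovery experiments.

What the generator does **not** emulate: turning steps between segments
(it inserts a silent gap), sensor drift and hysteresis, foot-size and
foot-progression-angle variation, pathological waveform shapes beyond
the parameters above, and any correlation between age/sex metadata and
the signals. Passing tests therefore demonstrate that the pipeline
recovers what the signal model encodes — not clinical validity on real
cohorts.

## 3. Preprocessing decisions

*Stance detection.* The contact threshold is 5% of the subject's median
peak stance force (estimated in a first pass from regions above 5% of
the series maximum), with hysteresis — the lift threshold is 0.8× the
strike threshold — and minimum contact and swing durations of 100 ms to
suppress chatter. Intervals are half-open `[strike, lift)` in samples.
The underlying event-detection protocol is not specified by the source
measurement system; this thresholding scheme is an explicit assumption,
validated against generator ground truth (strikes recovered within
±20 ms).

*Transient steps.* Walking segments begin and end at zero speed. The
first and last `k = 2` stances of each segment (in strike order, both
feet) are removed automatically — the lower bound of the customary
manual removal of two to four steps; `k` is configurable up to 4.
Subjects with fewer than 3 remaining stances on either foot are excluded
and logged.

*Segment assignment* uses the silent gap between segments: a stance
starting more than 1 s after every earlier lift opens a new segment.

## 4. Feature definitions and numerical choices

All 182 features, their categories, aggregations and physical dimensions
are enumerated by `feature_dictionary()`. Per-stance parameters are
aggregated with four statistics: mean over left stances, SD over left
stances, SD over all stances of both feet, and the left−right mean
difference. Where a parameter is undefined for a stance it is excluded
from aggregation; a feature with no valid stance at all becomes `NA` and
is imputed with the cohort median (`impute_features()`) or, inside
cross-validation, with the training-fold median — the validation fold
never informs the imputation.

Choices where the construction was genuinely open:

- *Sway surface*: convex-hull area of the 45 s COP path. A hull is well
  defined for self-intersecting sway paths; a bounding ellipse was the
  documented alternative and is not used.
- *Stance envelope*: per-sample maximum over the seven channels — the
  curve that sits on top of all sensor traces. Landmarks (two highest
  local maxima and the valley between them) are detected on a 5-sample
  moving average and refined on the raw envelope within the smoothing
  half-window; ties break toward the earlier sample.
- *Peak widths* are measured at 30% of each peak's height from zero,
  with interpolated crossings, bounded by the adjacent valley and the
  stance endpoints (when the valley sits above the 30% level the width
  is truncated at the valley).
- *Peak/valley ratios* are capped (default 50) when the valley height
  approaches zero; capped stances are counted in the QC log. Stances
  with no detectable valley are flagged unimodal and excluded.
- *Slope rates* are force change per second (N/s), not per normalised
  stance time.
- *AUC*: each stance is resampled to 100 points on normalised time
  [0, 1] by linear interpolation and integrated with the trapezoid rule
  on that axis, so the AUC carries force units (a constant 50 N stance
  has AUC 50 N).
- *Time of maximum*: first occurrence on plateaus, expressed as a
  fraction of stance time.
- *COP reference crossings* (x at the centre-midfoot / centre-forefoot y
  levels) use the first anterior-going crossing, linearly interpolated —
  an assumption when the path crosses a level more than once.
- *CPEI*: maximum perpendicular deviation of the stance COP path from
  its start→end chord, divided by the lateral–medial forefoot sensor
  distance of the layout.
- *Frequency analysis* runs on the concatenated trimmed walking segments
  (first retained strike to last retained lift per segment), de-meaned,
  rectangular window, zero-padded to a bin width ≤0.5 Hz; band
  statistics are taken over 2–10 Hz, with "power density" the trapezoid
  integral of power over the band.
- *Support transitions* of a stance are taken from the full detected
  stance set, not the trimmed one, so boundary stances keep both
  double-support episodes.

## 5. Classification

Each forest has 200 trees grown to purity (terminal node size 1, Gini
criterion, `floor(sqrt(p))` candidate features per split). Every tree
trains on a class-balanced bootstrap: a with-replacement sample of
minority-class size from each class. This down-sampling variant keeps
balanced accuracy honest under the 20/80 and 30/70 imbalances typical of
faller and frailty labels — on label-independent features the mean
balanced accuracy stays at 0.5.

Cross-validation uses stratified folds (the source protocol says only
"five equal subsamples"; stratification guarantees both classes in every
validation fold, which matters for small subgroups) and is repeated with
fresh splits; metrics are averaged over folds, then summarised over
repeats. The pooled confusion matrix accumulates validation predictions
over all folds and repeats and is reported row-normalised. A master seed
spawns recorded per-repeat seeds, so any report is exactly reproducible.

Feature importance is the mean decrease in Gini impurity of a forest
refit per repeat on the full data with that repeat's seed (whether
importances should come from CV-fold forests or full-data forests is
ambiguous in the source description; full-data refits use all available
signal and keep ranks independent of the fold geometry). Ranks
(1 = most important, ties broken by feature order) are averaged across
repeats.

Subgroup models mirror the published table layout: frailty on the whole
population and the ≥65, 65–69, 70–74, ≥75, women-≥65 and men-≥65
subgroups (7 models); fall history additionally on the frail-only and
non-frail-only subgroups (9 models). Subgroups with fewer subjects in a
class than folds are skipped with a logged reason.

## 6. Validation problem sizes

The package validates itself on synthetic cohorts sized to exercise each
property well: 50 subjects for event-detection recovery (≥95% of strikes
within ±20 ms, zero exclusions), 100 subjects and 20 CV repeats for the
null check (balanced accuracy 0.5 ± 0.05 with labels independent of
signals), and 200 subjects with a 30% injected group difference in
stance duration and peak/valley ratio for effect recovery (balanced
accuracy ≥0.85 and injected-parameter features in the importance
top-10). These sizes are the package's own validation choices; larger
cohorts sharpen all of these checks monotonically.

## 7. Known limitations

- The 182 features assume a two-peak stance envelope; heavily shuffling
  or pathological gait that produces unimodal envelopes reduces the
  wavelet category to imputed medians (the QC log counts such stances).
- COP quantities are layout-relative; absolute millimetre values are not
  comparable across different assumed sensor geometries.
- The classifier reports discrimination on the cohort given to it;
  nothing here is a clinical claim. Nested model selection and
  regression comparators are out of scope by design (hooks exist in the
  model-spec schema).
- Walking speed and stride length are not computable: a pressure insole
  carries no spatial calibration.
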