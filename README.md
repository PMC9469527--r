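# insolegait

Gait and balance analysis of 7-sensor plantar-pressure insole recordings,
with balanced random-forest classification of frailty and fall history.

## The problem

Frailty screening in older adults relies on questionnaires; falls are
recalled, not measured. Pressure-sensing insoles offer an objective
alternative: a subject stands quietly for 45 s and walks two 10 m
segments while each shoe records seven pressure channels (heel, lateral
midfoot, centre midfoot, lateral forefoot, centre forefoot, medial
forefoot, big toe) at 100 Hz. `insolegait` turns those 14 raw channels
into a fixed 182-dimension feature vector per subject and trains
class-balanced random forests to separate frail from non-frail subjects
(and fallers from non-fallers), reporting balanced accuracy, weighted F1
and impurity-based feature importances over repeated cross-validation.

Because raw clinical recordings of this kind are rarely shareable, the
package ships a synthetic cohort generator that emulates the insole
signal model — double-peaked stance force envelopes, alternating stances
with double support, standing centre-of-pressure (COP) sway, a 25–550 kPa
sensor range on a 10-bit scale — with ground-truth event times and
configurable group effects, so that every stage of the pipeline is
testable end to end.

## What it computes

- **Preprocessing** — pressure→force conversion (constant effective
  sensor area), strike/lift detection by adaptive force thresholding with
  hysteresis, removal of acceleration/deceleration steps, the ≥3 steps
  per foot inclusion rule, and the last-45 s standing window.
- **Features (182)** — standing COP sway (range on both axes, path
  length, covered surface; 4), frequency-domain statistics of the summed
  force series in 2–10 Hz (4), per-sensor peak/AUC statistics (84),
  single-foot COP trajectory parameters including the COP excursion
  index CPEI (52), gait-phase timing (8), and stance force-envelope
  landmarks: two peaks, the valley, peak/valley ratios, 30%-height peak
  widths and four slope rates (30).
- **Classification** — random forests of 200 trees, each tree grown to
  purity on a class-balanced bootstrap (majority class down-sampled per
  tree), validated by stratified 5-fold cross-validation repeated with
  fresh splits; balanced accuracy = mean per-class recall, weighted F1 =
  class-frequency-weighted F1. Feature importance is the mean decrease in
  Gini impurity, ranked per repeat and rank-averaged.

## Worked example

```r
library(insolegait)
library(dplyr)

cohort <- generate_cohort(generator_config(
  n_subjects = 40, seed = 42, frail_fraction = 0.35,
  effect_size_multipliers = list(frail = c(stance_duration_mean = 1.25))))
#> <insole cohort: 40 subjects (14 frail, 8 fallers), seed 42>

prep     <- preprocess_cohort(cohort)          # 0 subjects excluded
features <- impute_features(extract_features(prep))

fit <- cross_validate(features, "frail", n_repeats = 10, seed = 1)
fit
#> <balanced random forest CV: target frail, n = 40 (14 positive)
#>  balanced accuracy 0.894 +/- 0.022, weighted F1 0.910 +/- 0.019
#>  over 10 repeats of stratified 5-fold CV, 200 trees>

round(fit$confusion_norm, 2)
#>      pred
#> truth    0    1
#>     0 0.97 0.03
#>     1 0.19 0.81

imp <- importance_ranking(features, "frail", n_repeats = 10, seed = 1)
head(generics::tidy(imp), 3)
#> 1 wavelet.width_peak1.mean_left         2             0.962
#> 2 gait_phase.duration_s.mean_left       2.8           0.832
#> 3 wavelet.peak_distance.mean_left       3.4           0.831
```

The injected 25% slowing of frail stance duration is picked up both by
the classifier (balanced accuracy 0.89 on a 14/26 cohort) and by the
importance ranking, which puts stance-duration and envelope-timing
features on top. `autoplot(fit)` draws the row-normalised confusion
matrix, `autoplot(imp)` the leading features; `tidy()`/`glance()` return
per-repeat metrics and the one-row summary.

The full pipeline (cohort CSVs, stance table, feature table, model
reports, QC log) runs as one call:

```r
run_pipeline(pipeline_config(generator = list(n_subjects = 40, seed = 42)),
             outdir = "out")
```

or from a shell via the thin wrapper `inst/cli/insolegait.R`
(subcommands `run`, `generate`, `preprocess`, `extract`, `classify`,
`report`, `show-config`).

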