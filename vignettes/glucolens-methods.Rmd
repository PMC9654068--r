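---
title: "Digital biomarkers from wearable time series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital biomarkers from wearable time series: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

glucolens implements two analyses on free-living wearable cohorts:
detecting *eating moments* from a continuous glucose monitor (CGM) sampling
interstitial glucose every 15 minutes, and predicting and explaining
*concurrent* glucose levels from food-diary, activity-tracker and
sleep-monitor context. This vignette documents the models, the tunable
parameters, and the design decisions taken where several constructions were
defensible.

## The synthetic cohort and what it emulates

Raw multimodal cohorts of this kind are rarely public, so the package ships
a generator (`simulate_cohort()`) that produces the four observation
streams — CGM glucose, diary items, wrist-device activity samples, nightly
sleep records — from a known generative model, plus the subject-level
ground truth needed for recovery tests. The glucose trace is composed
additively:

$$
g_i(t) = b_i + \gamma_i\,(7 - s_{i,\text{prev}}) +
\sum_{m} A_{i,m}\, u\, e^{1-u} \Big|_{u = (t - t_m)/\tau_i}
- \beta_i\, \mathrm{EE}_i(t-1\mathrm{h}, t] + \varepsilon_i(t),
$$

with subject baseline $b_i \sim N(5.0,\,0.3)$ mmol/L, meal amplitudes
$A_{i,m} = s_i \cdot \mathrm{kcal}^{carb}_m / 100$ driven by a dimensionless
carbohydrate sensitivity $s_i \sim N(1.0,\,0.15)$ truncated at zero, a
gamma-type meal impulse response peaking at $\tau_i \approx 45$ min, an
activity term that depresses glucose by $\beta_i$ mmol/L per kcal of
trailing-hour energy expenditure (default $2\times10^{-3}$), a sleep term
of $\gamma_i$ mmol/L per hour of deficit against a neutral 7-h night
(default 0.05), and AR(1) sensor noise with marginal SD 0.15 mmol/L and
lag-1 correlation 0.5. Traces are clamped positive. Defaults produce
normoglycemic traces around 4–8 mmol/L for a 24-subject, 14-day design;
all knobs sit in `cohort_config()`.

Meals land at jittered breakfast/lunch/dinner slots (07:30/12:30/18:30,
SD 30 min) with up to two snacks, are pushed at least 45 min apart so
excursions stay separable for label tests, and are logged as 1–3 diary
items spaced 5 min apart with grams split evenly — so meal aggregation can
recover the planted meal exactly. Activity runs at a 5-min cadence with a
resting level near 6 kcal per sample and 0–2 daily bouts of 30–60 min in
which energy expenditure, acceleration counts and heart rate
($\approx 60 + 0.15\cdot\text{acn}$ bpm) rise together, giving the three
activity variables the correlation structure the grouped importance report
assumes. `inject_gaps()` removes rows in contiguous per-modality blocks,
emulating whole-device failure episodes.

What the generator does *not* emulate: insulin–glucose feedback dynamics
(no physiological ODE model), sensor drift or warm-up artifacts, meal
misreporting, circadian baseline variation, or stress and menstrual
covariates. Tests passing on this cohort therefore demonstrate that the
pipeline recovers planted structure faithfully — not that the models reach
any particular accuracy on real participants.

## Preprocessing rules

* **Meal aggregation.** Diary items chained while consecutive items are
  ≤ 15 min apart form one meal, stamped at the first item. Calories come
  from grams via Atwater factors (4/9/4 kcal per g carbohydrate/fat/
  protein); fractions are 0 for zero-calorie meals. A food-database lookup
  is out of scope, which is why the diaries carry grams.
* **Grids and joins.** All grids are half-open 15-min intervals
  `[t, t+15)`, timestamps UTC. Per interval, energy expenditure and
  acceleration are summed (extensive), heart rate is averaged (intensive).
  Each grid row receives the closest preceding sleep record no older than
  28 h, else missing.
* **Uninterrupted stretches.** A stretch is a maximal run of intervals
  where both the CGM and the activity device delivered data; one missing
  CGM sample breaks it (devices buffer at fixed cadence, so an absent
  sample is a real outage). The diary has no sampling cadence and is
  treated as always available while devices are worn. Stretches under 24 h
  are dropped; subjects are retained only when their stretches total
  strictly more than 7 days.
* **Splits.** Glucose prediction holds out each subject's last 3 days of
  available (in-stretch) data, measured from the stretch end in row counts
  (the calendar alternative differs only when gaps fall inside the final
  window). Meal detection trains on the first 4 days and tests on the next
  3, leaving any later data unused, mimicking the burden of diary keeping.

## Feature spaces

The meal-detection space is CGM-only: lead/lag glucose values of orders
1–6 (exactly the 90-min horizon at 15-min cadence), lead differences and
log-lead differences, *lagged* lead differences — read as
$g(t{+}k{-}1) - g(t{-}1)$, the 1-sample-lagged difference of the lead —
windowed means/SDs of the 90-min lead, lag and combined windows, relative
SDs, and lead/lag SD, max and min ratios (41 columns). Constant windows
use neutral conventions: $0/0$ ratios are 1, relative SDs with zero SD are
0, and any other non-finite ratio is missing. Features reaching across a
stretch boundary are missing, never imputed; the boosted trees route
missing values natively. A config switch can append the three per-interval
activity columns, but the default follows the CGM-only construction.

A grid row is a positive *eating moment* when a carbohydrate-containing
meal falls in its interval or an adjacent one — an isolated meal marks a
30-min segment (3 rows; 2 at a stretch edge). Carb-free meals label
nothing.

The glucose-prediction space has exactly 72 engineered predictors:
7 nutrition variables (4 kcal sums, 3 calorie-fraction means) and 3
activity variables (energy-expenditure and acceleration sums, heart-rate
mean) over 7 trailing windows — 30, 60, 90 min, 2, 3, 8, 24 h — plus sleep
duration and deep-sleep duration. Sums are used for extensive quantities,
means for fractions and heart rate; fraction means average only over
meal-carrying rows (0 on empty support, since a fraction is undefined
without intake). Windows cover `(t−W, t]` and never cross stretch
boundaries. Subject one-hot indicators ride alongside the 72 (they encode
the subject-specific intercept, not an engineered signal), and the target
is natural-log glucose.

## Models

Both tasks use gradient-boosted trees (xgboost), single-threaded and
seeded throughout. Recursive feature elimination drops the lowest-gain 20%
of remaining features per iteration (ties broken by column order, at least
one dropped, down to one feature), scoring every subset size with 10-fold
cross-validation at fixed default hyperparameters and 100 rounds. The
selected set is the *smallest* whose mean CV error is within 10% of the
best subset's — "within 10%" interpreted on the error scale
(error ≤ 1.10 × best). Folds are row-random (stratified by label for
classification) and are reused across subset sizes; RFE and tuning draw
independent seeded partitions. Subject- or time-blocked CV is a deliberate
non-default: the reference setup pools rows.

Hyperparameter search minimizes 10-fold CV classification error over a
small exhaustive grid (max_depth ∈ {3, 6}, eta ∈ {0.1, 0.3},
min_child_weight ∈ {1, 5}, subsample ∈ {0.8, 1}) for meal detection, and
CV MAE of log glucose via random search (default 60 draws; the pipeline
default is 20 for desk-scale runtime) over max_depth 2–8, log-uniform eta
0.03–0.3, min_child_weight 1–10, subsample and colsample_bytree 0.6–1 for
regression. Ties go to lower complexity (smaller depth, then smaller
min_child_weight), then draw order. The classification decision threshold
is 0.5 with no re-weighting; class imbalance is surfaced by reporting
sensitivity and specificity separately.

## Explanation

Per-instance attributions use the exact path-dependent tree-Shapley
algorithm, implemented in C++ in double precision. The tree structure is
read from the booster's raw JSON serialization, whose numbers are the
shortest round-trip representation of the internal float32 values; casting
back to float32 reproduces the exact split thresholds, and split
comparisons are done in float32, so the traversal agrees with the booster
bit-for-bit up to its own float32 accumulation. Local accuracy — base
value plus row contributions equals the ensemble score — holds to
double-precision rounding ($\sim 10^{-14}$), and the package's tests
cross-check contributions against the booster's built-in float32
implementation at $2\times10^{-5}$. The path-dependent (cover-weighted)
formulation is used, not the interventional one with an explicit
background dataset, matching the cited tree-ensemble algorithm.

Overall importance is the mean absolute contribution per feature over all
training rows, grouped for reporting: windows ≤ 3 h are short-term, 8 h and
24 h long-term; acceleration maps to activity, energy expenditure and
heart rate to cardiometabolic, calorie and fraction features to nutrition;
sleep columns and subject indicators form their own groups. Unmapped
features raise an error rather than pooling silently.

Glucose peaks are strict local maxima (interior plateaus count once, at
their first sample) of a subject's observed series whose value exceeds
Q3 + IQR of that subject's full training series, type-7 quantiles. All
qualifying maxima count — no minimum peak distance is imposed. Subjects
with fewer than 10 peaks are excluded from per-peak reporting. Each peak's
top-5 features by absolute contribution (ties by column order; subject
indicators are eligible, representing the subject-specific intercept) are
tallied per subject.

## Evaluation

Classification reports pooled accuracy/sensitivity/specificity with
per-subject min–max ranges (the interval convention used for headline
rates; per-subject rates with undefined denominators are excluded with a
warning). Regression reports per-subject MAE on the mmol/L scale after
back-transforming, summarized as unweighted mean ± SD across subjects.
Bland–Altman agreement uses differences predicted − observed, bias = mean
difference, and 2.5th/97.5th *percentile* limits of agreement (type-7),
not ±1.96 SD.

## Numerical choices and degenerate inputs

Stretches shorter than 13 samples cannot host the ±6-sample CGM windows
and are dropped with a warning. Rows lacking a full trailing window are
missing, not imputed. Constant series produce no peaks (threshold equals
the constant; maxima are strict). Targets with missing values are dropped
with a logged count before fitting. All stochastic stages (simulation,
gaps, folds, random search, subsampling) derive 32-bit child seeds from
one master seed, and identical configurations reproduce bit-identical
tables, models and reports; training is also invariant to row order.

## Problem sizes used by the shipped checks

The package's own acceptance checks run on a 12-subject × 14-day cohort —
chosen as a desk-scale instance of the study design — with feature-builder
oracle sweeps over 200 random stretches and 500 random peak series, and a
10-seed end-to-end recovery experiment (held-out detection rates above
no-information rates, held-out MAE below a per-subject training-mean
baseline, and nutrition outranking activity in grouped importance when the
generator's activity effect is disabled). The reproduction script applies
full RFE and tuning at the same scale.

## Known limitations

The generator's additive, noise-light physiology makes both tasks easier
than real free-living data; reported synthetic accuracies are upper bounds
on what field data would give. RFE's elimination schedule (20% per step)
and the tuning grids are pragmatic defaults, not swept; fraction features
carry a 0-on-empty-support convention that a model could in principle
exploit; and the pipeline predicts concurrent glucose, not future values —
forecasting is explicitly out of scope.
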