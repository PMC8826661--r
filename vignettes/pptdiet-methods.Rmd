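---
title: "Methods: glycemic analytics for personalized postprandial-targeting diet trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glycemic analytics for personalized postprandial-targeting diet trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pptdiet)
```

# The analysis problem

`pptdiet` implements the computational pipeline of a dietary-intervention
trial design used in newly diagnosed type 2 diabetes: a randomized two-period
crossover comparing a personalized postprandial-targeting (PPT) diet against a
Mediterranean-style (MED) diet, followed by a longer single-arm PPT phase.
Participants wear continuous glucose monitors (CGM, nominal 15-minute
sampling) and log meals on a smartphone; blood panels and stool samples are
collected at the phase boundaries. The pipeline turns those raw streams into
the trial's endpoints: CGM-derived glycemic measures, adherence grades,
crossover and longitudinal effect estimates, postprandial-response prediction
quality, and microbiome-change associations.

Because participant-level data from such trials are not public, the package
ships a synthetic cohort generator with known ground truth; every stage of the
pipeline is validated against it and against independent brute-force oracles.

# CGM measures

**Meal PPGR.** The postprandial glucose response of a logged meal is the
incremental area under the glucose curve in the 2 h after the meal was
logged, in mg/dl × h. The baseline is the glucose at the meal-log time,
linearly interpolated between neighbouring readings. Area below the baseline
contributes zero — the common incremental-AUC convention; the signed
"net AUC" is available via `clip_below_baseline = FALSE` for sensitivity.
The positive-part integral is computed analytically per segment (crossings of
the baseline are solved exactly on the linear interpolant), so agreement with
a dense-grid oracle is at numerical precision, not discretization precision.
A meal needs at least two readings in its window and 75% coverage (both
configurable) to be computable; uncomputable meals are flagged and counted,
never silently dropped.

**Averaged PPGR.** The connection-wide analogue: every sensor connection is
partitioned into consecutive non-overlapping blocks of 9 readings (≈2 h at
15-minute cadence), each block's iAUC is taken against its first reading, and
the block mean is reported. Whether the original measure used disjoint blocks
or a sliding window is not recoverable from the trial's description; disjoint
blocks are the default and `sliding = TRUE` gives the alternative.

**Glucose CV.** Sample standard deviation over mean of all readings in the
period — scale-free, so sensor calibration offsets that rescale glucose leave
it unchanged.

**Time above thresholds.** Daily hours with glucose strictly above each of
140, 150, 160, 170, 180 mg/dl. Between consecutive readings of one
connection the trace is linear, so threshold crossings are located exactly;
segments are split at local midnight so each calendar day accrues only its
own time. A day qualifies with ≥48 readings (half the nominal 96/day), a
guard against sensor-swap days; within a qualifying day the above-threshold
time is scaled to a 24-h day by the observed time, and days are averaged.
Timestamps are handled timezone-naive, so "daily" means local calendar day.

**Sensor connections.** When a CGM file carries no connection labels, wear
periods are inferred from gaps longer than 3 h (configurable): at 15-minute
cadence a multi-hour gap is an unambiguous detachment or replacement.

# Adherence grading

Each meal score *s* ∈ {1..5} (1 = best for that person) maps to a grade:
100, 80, 50, 25, 0. The period **composition grade** is the calorie-weighted
mean of meal grades, with each meal's energy clamped into the (100, 500) kcal
trim interval before weighting so that no single large meal dominates and
small snacks still count. If fewer than 100 kcal were logged in total
(untrimmed — the rule is about logging volume), no grade is computed.

The **calorie grade** compares the period's mean daily intake with the
prescribed caloric target CT: deviation d = |intake − CT| / CT earns grade
100 at d ≤ 0.15, zero at d ≥ 0.60, and linear interpolation
100 (0.60 − d)/0.45 between. Two readings of the published rule are not
fully determined and are fixed here as package conventions: the deviation is
symmetric (over- and under-eating penalized alike), and it is evaluated on
the period-mean daily intake rather than day by day.

The two-week feedback report combines both grades with the k best and worst
meals (ties broken toward the smaller meal on the best list, the larger on
the worst list). Per-participant mean composition grades feed the adherence
median split (ties to the high group) used to compare clinical changes
between more- and less-adherent participants.

# Menus and meal scores

A MED menu is validated on its whole candidate pool by energy-weighted
macronutrient shares (4 kcal/g carbohydrate and protein, 9 kcal/g fat):
carbohydrate 45–65% and protein 15–20% of energy are inclusive ranges; fat
< 35% and saturated fat < 10% are strict bounds.

The PPT meal score ranks a meal's predicted PPGR within the person's own
distribution of predictions over a reference meal bank. The published
score thresholds are not public, so the package defines the score as the
quantile bin at quintile cut-points (configurable to arbitrary cut-points or
to absolute thresholds via a degenerate reference), ties taking the lower
score. PPT menus are filled slot-by-slot with the lowest-score candidates,
ties broken by lower predicted PPGR then name, and a slot that cannot be
filled at the maximum admissible score (default 2) is an error rather than a
silent relaxation.

The dominant food of a meal — used to match "the same meal" across people —
is the single item strictly exceeding 70% of meal energy.

# PPGR prediction and evaluation

The clinical reference predictor is carbohydrate counting: ordinary least
squares of measured iAUC on carbohydrate grams. The feature-based predictor
is a gradient-boosted ensemble of shallow regression trees (200 trees, depth
3, learning rate 0.05, 80% row subsampling, fixed seed) over meal
macronutrients, clinical features and taxa abundances. It is a surrogate
with the same interface and feature classes as published microbiome-aware
PPGR predictors, not a reproduction of any trained model; its hyperparameters
were fixed a priori at conventional values for small tabular problems.

Evaluation is leave-one-person-out: for each person the model is refit
without any of their meals and their meals are predicted, which is the
honest generalization question for a new patient. Explained variance is
reported as 100 × (pooled Pearson r)², matching the predicted-vs-measured
scatter convention; the 1 − SSE/SST form is available via `r2_form = "ss"`
because the two differ for miscalibrated predictors. A constant prediction
vector has no defined correlation and is reported as 0%. Fold integrity is
auditable: the evaluation object records which participants each fold was
trained on.

# Trial statistics

Crossover effects are always PPT − MED. The primary estimate is the paired
t: mean and SD of within-person differences. The rank-based variant applies
the one-sample rank test (Wilcoxon signed-rank) to the same differences. The
sensitivity suite fits linear mixed models with a participant random
intercept — diet only; diet + period; diet + period + sequence — plus a
parallel-groups check on period-1 data only. The exact mixed-model
specifications used in such trials are rarely printed; this four-model suite
is the canonical crossover set and is labelled an assumption.

Six-month changes use the one-sample t test on T6 − T0, with the rank
alternative for skewed outcomes such as HOMA-IR
(glucose × insulin / 405, the standard mass-unit formula). Remission is
counted among participants starting at or above HbA1c 6.5% (inclusive) who
end strictly below it. No multiplicity correction is applied across clinical
outcomes; FDR control is reserved for the microbiome screen, mirroring
common practice in these trials.

The intra- vs inter-person variability analysis groups PPGRs by
(person, dominant food): intra CV is the per-group sd/mean averaged over
groups, inter CV is the across-person sd/mean of per-person median iAUC per
food, and the two are compared by a paired two-sided t test across foods.
Under a person-level effect exceeding meal-level noise (τ > σ), intra < inter
is recovered in the median over simulation seeds.

# Microbiome associations

Shannon diversity is reported in nats (the log base is a convention; natural
log is used and stated). The Firmicutes/Bacteroidetes ratio aggregates by
phylum lineage with no pseudocount — a zero Bacteroidetes sum yields an
undefined ratio rather than an arbitrary finite one. The
propionate-producer aggregate sums a configurable genus set; the shipped
default (`propionate_producers()`) is a literature-derived convention and
should be replaced when a study defines its own membership.

Change–outcome screening computes Pearson correlations between per-taxon
abundance changes and clinical changes, with Benjamini–Hochberg adjustment
within each phylogenetic level across all of that level's (taxon, outcome)
pairs — one family per level, the most conservative reading of "per level";
per-(level, outcome) families are available behind a flag. Changes are raw
relative-abundance differences; abundances are compositional, so a CLR-style
transform is a reasonable alternative the user can apply upstream. The
default significance threshold is q ≤ 0.15, the screening-level FDR such
exploratory microbiome analyses use. Zero-variance pairs are skipped with a
warning, and pairs need ≥4 complete participants.

The baseline diversity-vs-outcome view sorts participants by the outcome and
overlays a centred 5-person rolling mean of diversity, reporting the raw
Pearson correlation alongside (never on the smoothed values, which would
overstate it).

# The synthetic cohort generator

Defaults are the study conditions of the emulated trial: 23 participants
split 11/12 between PPT-MED and MED-PPT sequences, 14-day periods at
15-minute sampling, person mean glucose 150 ± 19 mg/dl, an injected
PPT-minus-MED effect of −20 mg/dl × h on average PPGR with within-person
difference SD 16, six-month clinical effects such as HbA1c −0.39 ± 0.48%
and FPG −16.4 ± 24.2 mg/dl on baselines of 6.8 ± 0.4% and 149.7 ± 19 mg/dl,
and arm macronutrient compositions of 46%/22% of energy from carbohydrate
(MED/PPT) and 29%/51% from fat. Fasting insulin (12 ± 5 µU/ml) is not part
of the printed cohort summary and was chosen once as a realistic value for
unmedicated T2DM.

Design choices worth knowing:

* **Excursion shape.** Each meal imprints a raised-cosine bump spanning
  exactly the 2-h window whose peak equals the meal's generative PPGR: the
  bump's incremental area is peak × 1 h in closed form, and the trapezoid
  rule integrates it *exactly* on the 15-minute grid (the cosine component
  sums to zero on a uniform partition of its period). Generative PPGRs are
  therefore recoverable, making the CGM metrics falsifiable by round trip.
* **Sensor wander.** The AR(1) baseline wander is deliberately small
  (φ = 0.3, innovation SD 0.5 mg/dl; stationary SD ≈ 0.5 mg/dl) so a meal's
  measured PPGR stays within a few percent of its generative value. Larger,
  realistic sensor noise would only mask implementation errors — the
  generator's job is validation, not sensor simulation. Person-level
  variability enters through the response model (person effect SD 12,
  person × food SD 10, residual SD 8).
* **Confound-free effect injection.** The two arms differ sharply in
  carbohydrate content by construction, so a naive "slope × grams" response
  would confound the arm contrast with carbohydrates. The generator instead
  applies the carbohydrate slope to period-centred grams (within-arm
  variation) and carries the entire between-arm contrast in the injected
  diet effect, so the crossover estimand equals the configured −20 exactly.
* **Injected taxa associations.** Target-taxon changes are constructed from
  the standardized clinical change with an exactly orthogonalized noise
  component, so the pre-renormalization correlation equals the configured r;
  compositional renormalization then attenuates it slightly (the recovery
  test brackets, rather than pins, the configured value).

What the generator does *not* emulate: glucose–insulin physiology (no ODE
dynamics, no circadian insulin sensitivity), logging noise and missed meals,
sensor error structure (MARD-style proportional error, compression lows),
and ecological structure in the microbiome beyond Dirichlet composition.
Passing the pipeline's tests therefore demonstrates correctness of the
computations under clean generative conditions, not robustness to every
artifact of real CGM and food-diary data.

# Validation suite and problem sizes

The statistical guarantees are exercised at sizes chosen to give tight Monte
Carlo error while keeping the suite quick on one CPU: effect recovery at
n = 23 over 200 replicates (mean estimate within ±2 mg/dl × h of the
injected −20; 95% CI coverage ≥ 90%); type-I calibration of the paired t
over 1000 null replicates (rejection rate 0.05 ± 0.02); BH false-discovery
proportion over 1000 global-null replicates of a 16-participant, 15-taxon,
2-outcome screen (mean FDP ≤ 0.15 + 3 MC SEs); surrogate-vs-baseline
comparisons over 5 seeds (strict-majority wins); and the full CGM pipeline
end-to-end once at n = 8 with 3-day periods. CGM metrics are checked against
brute-force oracles (dense-grid integration; numeric root-finding at
threshold crossings) on 50 randomized one-day traces at relative error
< 1e−6.

# Known limitations

* The adherence calorie-penalty form matches the two published knots; if the
  original system interpolated on a different scale between them, mid-range
  grades differ (endpoints cannot).
* The meal-score quintile convention stands in for unavailable published
  thresholds; absolute mg/dl × h cut-offs may have been used originally.
* The boosted surrogate is not the published PPGR predictor and makes no
  claim to its reported explained-variance figures; it exists so the
  prediction-evaluation machinery is exercised by a model of the same class.
* Mixed-model p-values use the lmerTest Satterthwaite approximation; at
  very small n exact permutation would be preferable.
* Taxa changes are raw compositional differences; strong compositional
  effects (one taxon's bloom depressing all others) can induce spurious
  negative associations that a log-ratio analysis would avoid.
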