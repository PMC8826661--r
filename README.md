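# pptdiet

Analysis pipeline for dietary-intervention trials in newly diagnosed type 2
diabetes that compare a **personalized postprandial-targeting (PPT) diet**
against a **Mediterranean-style (MED) diet** in a randomized two-period
crossover, optionally followed by a longer single-arm PPT phase. It is
written for trial analysts and methods researchers who have continuous
glucose monitoring (CGM) traces, smartphone meal logs, clinical panels and
stool-derived taxa tables, and need the full chain from raw streams to the
trial's endpoints.

## What it computes

* **CGM glycemic measures** — per-meal postprandial glucose response
  (PPGR), quantified as the incremental area under the glucose curve in the
  2 h after the meal (iAUC, mg/dl × h, baseline interpolated at the log
  time, below-baseline area clipped); block-wise averaged PPGR (iAUC of
  every 9 readings per sensor connection); glucose coefficient of variation
  (sd/mean); daily hours with glucose strictly above 140–180 mg/dl with
  exact interpolation at threshold crossings; hourly PPGR profiles and PPGR
  percentiles.
* **Adherence grading** — meal scores 1–5 map to grades 100/80/50/25/0; the
  period composition grade is the calorie-weighted mean with per-meal energy
  clamped to (100, 500) kcal; the calorie grade applies a two-knot linear
  penalty on deviation from the caloric target (100 within 15%, 0 beyond
  60%); two-week feedback reports with best/worst meal lists.
* **Menu engineering** — quintile-based meal scoring from predicted PPGRs,
  PPT menu construction, MED menu validation against macronutrient bounds
  (carbohydrate 45–65%, protein 15–20%, fat < 35%, saturated fat < 10% of
  energy), dominant-food identification (> 70% of meal energy).
* **PPGR prediction** — carbohydrate-counting baseline vs a gradient-boosted
  tree surrogate over meal, clinical and microbiome features, evaluated by
  leave-one-person-out cross-validation with pooled explained variance.
* **Trial statistics** — paired/rank/mixed-model crossover estimates
  (PPT − MED) with a four-model sensitivity suite, one-sample six-month
  change tests, HOMA-IR, diabetes remission rates (HbA1c 6.5% threshold),
  adherence median-split comparisons, intra- vs inter-person PPGR
  variability for dominant-food-matched meals.
* **Microbiome association** — Shannon diversity (nats),
  Firmicutes/Bacteroidetes ratio, functional aggregates, and taxa-change vs
  clinical-change Pearson screening with Benjamini–Hochberg FDR at q ≤ 0.15
  per phylogenetic level.
* **Synthetic cohorts** — a seeded generator producing CGM traces with
  meal-locked excursions of known iAUC, meal logs, clinical panels with
  injected effects, and compositional taxa tables with injected
  change–outcome correlations, so the whole pipeline is testable with known
  ground truth.

## Worked example

Generate a small synthetic cohort, measure PPGRs from the traces, and
estimate the crossover diet effect:

```r
library(pptdiet)
library(dplyr)

sim <- generate_cohort(cohort_config(n_participants = 6,
                                     n_sequence_ppt_first = 3),
                       seed = 1, period_days = 3)
sim$bundle
#> <trial_bundle> 6 participants, 3456 CGM readings, 144 meals, 18 clinical rows, 204 taxa rows

glycemic_summary(sim$bundle$traces, sim$bundle$meals)
#>   participant_id mean_glucose glucose_cv hours_above_140 averaged_ppgr
#> 1 P01                    147.     0.120             7.30         11.4
#> 2 P02                    163.     0.116            24            12.2
#> 3 P03                    143.     0.135             6.27         12.4
#> ...

pp <- ppgr_table(sim$bundle$traces, sim$bundle$meals)
measured <- pp |>
  filter(computable) |>
  mutate(diet = ifelse(grepl("^ppt", meal), "PPT", "MED")) |>
  group_by(participant_id, diet) |>
  summarise(value = mean(iauc), .groups = "drop") |>
  inner_join(distinct(sim$records[, c("participant_id", "sequence",
                                      "diet", "period")]),
             by = c("participant_id", "diet"))
crossover_effect(measured, "paired_t", outcome = "mean_meal_ppgr")
#>   outcome        model    estimate dispersion   p_value     n
#> 1 mean_meal_ppgr paired_t    -21.4       2.95 0.0000103     6
```

The estimate is the mean within-person PPT − MED difference in average meal
PPGR: here −21.4 mg/dl × h against an injected ground truth of −20 (the
generator's default diet effect), with the paired-t dispersion and p-value
alongside. The adherence grading reproduces its defining worked example —
three meals of 600, 1000 and 80 kcal at scores 2, 5 and 1 grade to

```r
composition_grade(tibble::tibble(kcal = c(600, 1000, 80),
                                 meal_score = c(2L, 5L, 1L)))
#> [1] 45.45455
```

i.e. (500×80 + 500×0 + 100×100)/(500 + 500 + 100) after energy trimming.

## Documentation

The methods vignette (`vignettes/pptdiet-methods.Rmd`) documents the models
and conventions in detail: iAUC and time-above integration, the grading
formulas, the quintile meal-score convention, the crossover sensitivity
suite, FDR families, and the synthetic generator's design (excursion shapes
with closed-form areas, confound-free effect injection) together with its
limitations.
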