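# Crossover and 6-month statistical analyses.
#
# Crossover records carry one outcome value per participant per diet period;
# effects are always expressed as PPT minus MED, so a negative estimate
# favors the personalized diet.

#' Crossover treatment effect
#'
#' Estimates the PPT-vs-MED effect on one outcome from a two-period
#' crossover. Available models:
#'
#' * `paired_t`: mean and SD of the within-person (PPT - MED) differences
#'   with a two-sided paired t test; the estimate equals the mean difference
#'   exactly.
#' * `mann_whitney`: Wilcoxon signed-rank test of the within-person
#'   differences against zero (the rank-based analogue of the paired test).
#' * `lmm`: linear mixed model with a diet fixed effect and a participant
#'   random intercept.
#' * `lmm_period`: as `lmm` plus a period fixed effect.
#' * `lmm_sequence`: as `lmm_period` plus a sequence (allocation) fixed
#'   effect.
#' * `first_period`: parallel-groups check using period-1 data only
#'   (two-sample Welch t test).
#'
#' The four model variants beyond the paired t form the crossover
#' sensitivity suite. Participants missing a period are dropped with a
#' warning (except in `first_period`, which needs only period 1).
#'
#' @param records tibble with `participant_id`, `diet` (`"PPT"`/`"MED"`),
#'   `period` (1 or 2), `sequence` (`"PPT-MED"`/`"MED-PPT"`), `value`
#' @param model one of `"paired_t"`, `"mann_whitney"`, `"lmm"`,
#'   `"lmm_period"`, `"lmm_sequence"`, `"first_period"`
#' @param outcome optional outcome label carried into the result
#' @return tibble with `outcome`, `model`, `estimate` (PPT - MED),
#'   `dispersion` (SD of within-person differences, or model SE), `p_value`,
#'   `n`
#' @export
crossover_effect <- function(records,
                             model = c("paired_t", "mann_whitney", "lmm",
                                       "lmm_period", "lmm_sequence",
                                       "first_period"),
                             outcome = "outcome") {
  model <- match.arg(model)
  assert_cols(records, c("participant_id", "diet", "value"), "crossover records")
  records <- records[!is.na(records$value), , drop = FALSE]

  if (model == "first_period") {
    assert_cols(records, "period", "crossover records")
    p1 <- records[records$period == 1, , drop = FALSE]
    tt <- stats::t.test(p1$value[p1$diet == "PPT"], p1$value[p1$diet == "MED"])
    return(tibble::tibble(
      outcome = outcome, model = model,
      estimate = unname(diff(rev(tt$estimate))),
      dispersion = unname(tt$stderr), p_value = tt$p.value,
      n = nrow(p1)
    ))
  }

  wide <- tidyr::pivot_wider(
    records[, c("participant_id", "diet", "value")],
    names_from = "diet", values_from = "value"
  )
  incomplete <- is.na(wide$PPT) | is.na(wide$MED)
  if (any(incomplete)) {
    rlang::warn(sprintf("%d participant(s) missing a period dropped", sum(incomplete)))
    wide <- wide[!incomplete, , drop = FALSE]
  }
  if (nrow(wide) < 3L) rlang::abort("need >= 3 participants with both periods")
  diffs <- wide$PPT - wide$MED

  if (model == "paired_t") {
    tt <- if (stats::sd(diffs) == 0) {
      list(p.value = if (mean(diffs) == 0) 1 else 0) # degenerate: no sampling noise
    } else stats::t.test(diffs)
    return(tibble::tibble(outcome = outcome, model = model,
                          estimate = mean(diffs), dispersion = stats::sd(diffs),
                          p_value = tt$p.value, n = length(diffs)))
  }
  if (model == "mann_whitney") {
    wt <- if (all(diffs == 0)) list(p.value = 1) else
      suppressWarnings(stats::wilcox.test(diffs, mu = 0))
    return(tibble::tibble(outcome = outcome, model = model,
                          estimate = stats::median(diffs),
                          dispersion = stats::sd(diffs),
                          p_value = wt$p.value, n = length(diffs)))
  }

  # linear mixed model variants
  assert_cols(records, c("period", "sequence"), "crossover records")
  dat <- records[records$participant_id %in% wide$participant_id, , drop = FALSE]
  dat$diet <- factor(dat$diet, levels = c("MED", "PPT"))
  dat$period <- factor(dat$period)
  dat$sequence <- factor(dat$sequence)
  form <- switch(model,
    lmm = value ~ diet + (1 | participant_id),
    lmm_period = value ~ diet + period + (1 | participant_id),
    lmm_sequence = value ~ diet + period + sequence + (1 | participant_id)
  )
  fit <- suppressMessages(lmerTest::lmer(form, data = dat))
  cf <- stats::coef(summary(fit))["dietPPT", ]
  tibble::tibble(outcome = outcome, model = model,
                 estimate = unname(cf["Estimate"]),
                 dispersion = unname(cf["Std. Error"]),
                 p_value = unname(cf["Pr(>|t|)"]),
                 n = length(unique(dat$participant_id)))
}

#' Six-month change in an outcome
#'
#' One-sample test of the per-participant change (end minus start) against
#' zero: a two-sided one-sample t test by default, or the rank-based
#' alternative (Wilcoxon signed-rank) used for skewed outcomes such as
#' HOMA-IR.
#'
#' @param panels tibble with `participant_id`, `timepoint` and the outcome
#'   column
#' @param outcome name of the outcome column
#' @param from,to timepoint labels of the start and end (defaults `"T0"`,
#'   `"T6"`)
#' @param test `"t"` (default) or `"wilcoxon"`
#' @return tibble with `outcome`, `estimate` (mean change), `dispersion`
#'   (SD of changes), `p_value`, `n`
#' @export
longitudinal_change <- function(panels, outcome, from = "T0", to = "T6",
                                test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  assert_cols(panels, c("participant_id", "timepoint", outcome), "clinical panels")
  wide <- tidyr::pivot_wider(
    panels[, c("participant_id", "timepoint", outcome)],
    names_from = "timepoint", values_from = dplyr::all_of(outcome)
  )
  if (!all(c(from, to) %in% names(wide))) {
    rlang::abort(sprintf("timepoints '%s' and '%s' not both present", from, to))
  }
  change <- wide[[to]] - wide[[from]]
  dropped <- sum(is.na(change))
  if (dropped > 0L) {
    rlang::warn(sprintf("%d participant(s) missing a timepoint dropped", dropped))
  }
  change <- change[!is.na(change)]
  if (length(change) < 3L) rlang::abort("need >= 3 participants with both timepoints")
  p <- if (stats::sd(change) == 0) {
    if (mean(change) == 0) 1 else 0 # degenerate: identical change for all
  } else if (test == "t") {
    stats::t.test(change)$p.value
  } else {
    suppressWarnings(stats::wilcox.test(change, mu = 0)$p.value)
  }
  tibble::tibble(outcome = outcome, estimate = mean(change),
                 dispersion = stats::sd(change), p_value = p,
                 n = length(change))
}

#' Homeostatic model assessment of insulin resistance
#'
#' The standard mass-unit formula: fasting plasma glucose (mg/dl) times
#' fasting insulin (uU/ml) divided by 405. Calibrated so that FPG 90 mg/dl
#' with insulin 4.5 uU/ml gives 1.0.
#'
#' @param fpg fasting plasma glucose, mg/dl (> 0)
#' @param insulin fasting insulin, uU/ml (> 0)
#' @return HOMA-IR (unitless)
#' @export
homa_ir <- function(fpg, insulin) {
  if (any(fpg <= 0) || any(insulin <= 0)) {
    rlang::abort("FPG and insulin must be positive")
  }
  fpg * insulin / 405
}

#' Diabetes remission rate
#'
#' Fraction of participants who started at or above the HbA1c diagnostic
#' threshold (default 6.5%) and ended below it. A participant at exactly the
#' threshold at baseline enters the denominator; one at exactly the
#' threshold at the end does not count as remitted (strict `<`).
#'
#' @param baseline_hba1c,end_hba1c paired numeric vectors of HbA1c (%)
#' @param threshold diagnostic threshold (default 6.5)
#' @return list with `numerator`, `denominator`, `fraction` (`NA` when no
#'   participant starts at or above threshold)
#' @export
remission_rate <- function(baseline_hba1c, end_hba1c, threshold = 6.5) {
  stopifnot(length(baseline_hba1c) == length(end_hba1c))
  ok <- !is.na(baseline_hba1c) & !is.na(end_hba1c)
  at_risk <- ok & baseline_hba1c >= threshold
  remitted <- at_risk & end_hba1c < threshold
  denom <- sum(at_risk)
  list(numerator = sum(remitted), denominator = denom,
       fraction = if (denom == 0) NA_real_ else sum(remitted) / denom)
}

#' Compare 6-month changes between adherence subgroups
#'
#' Splits participants at the median of their mean feedback grade (the
#' median-valued participant joins the high group) and compares each
#' outcome's 6-month change between high- and low-adherence groups with a
#' two-sample Welch t test. A split leaving either group with fewer than 2
#' participants is degenerate and an error.
#'
#' @param changes tibble with `participant_id` and one column per outcome
#'   change
#' @param grades tibble with `participant_id`, `mean_grade` (see
#'   [mean_feedback_grade()])
#' @param outcomes character vector of change columns to compare (default:
#'   all numeric columns of `changes`)
#' @return tibble with one row per outcome: group means/SDs, `p_value`,
#'   group sizes, and the grade median used
#' @export
adherence_subgroup_compare <- function(changes, grades, outcomes = NULL) {
  merged <- dplyr::inner_join(changes, grades, by = "participant_id")
  med <- stats::median(merged$mean_grade)
  high <- merged$mean_grade >= med
  if (sum(high) < 2L || sum(!high) < 2L) {
    rlang::abort("degenerate adherence split: fewer than 2 participants in a subgroup")
  }
  if (is.null(outcomes)) {
    outcomes <- setdiff(names(changes)[vapply(changes, is.numeric, logical(1))],
                        "participant_id")
  }
  purrr::map_dfr(outcomes, function(oc) {
    hi <- merged[[oc]][high]; lo <- merged[[oc]][!high]
    p <- if (stats::sd(hi) == 0 && stats::sd(lo) == 0) {
      if (mean(hi) == mean(lo)) 1 else 0
    } else {
      stats::t.test(hi, lo)$p.value
    }
    tibble::tibble(outcome = oc, grade_median = med,
                   mean_high = mean(hi), sd_high = stats::sd(hi),
                   mean_low = mean(lo), sd_low = stats::sd(lo),
                   p_value = p, n_high = sum(high), n_low = sum(!high))
  })
}

#' Intra- vs inter-person variability of PPGRs to matched meals
#'
#' For meals sharing a dominant food across persons: the intra-person CV is
#' the sd/mean of each (person, food) group's iAUCs, averaged over groups;
#' the inter-person CV is, per food, the sd/mean across persons of the
#' per-person median iAUC, averaged over foods. Only (person, food) groups
#' with at least `min_meals` meals and foods with at least `min_persons`
#' such persons contribute; others are skipped with a warning. The two CVs
#' are compared with a two-sided paired t test on per-food values (each
#' food contributes its mean intra CV and its inter CV).
#'
#' @param ppgrs tibble with `participant_id`, `dominant_food`, `iauc`
#' @param min_meals minimum matched meals per (person, food) group
#' @param min_persons minimum persons per food
#' @return list with `intra_cv` (mean), `inter_cv` (mean), `p_value`,
#'   `per_food` tibble
#' @export
intra_inter_cv <- function(ppgrs, min_meals = 2, min_persons = 2) {
  ppgrs <- ppgrs[!is.na(ppgrs$dominant_food) & !is.na(ppgrs$iauc), , drop = FALSE]
  groups <- ppgrs |>
    dplyr::group_by(.data$dominant_food, .data$participant_id) |>
    dplyr::summarise(n = dplyr::n(), intra = cv_of(.data$iauc),
                     med = stats::median(.data$iauc), .groups = "drop") |>
    dplyr::filter(.data$n >= min_meals)
  per_food <- groups |>
    dplyr::group_by(.data$dominant_food) |>
    dplyr::summarise(n_persons = dplyr::n(),
                     intra_cv = mean(.data$intra),
                     inter_cv = cv_of(.data$med), .groups = "drop")
  skipped <- per_food$n_persons < min_persons
  if (any(skipped)) {
    rlang::warn(sprintf("%d food(s) with insufficient replication skipped",
                        sum(skipped)))
  }
  per_food <- per_food[!skipped, , drop = FALSE]
  if (nrow(per_food) == 0L) {
    rlang::abort("no dominant food has sufficient replication across persons")
  }
  d <- per_food$intra_cv - per_food$inter_cv
  p <- if (nrow(per_food) < 2L || stats::sd(d) == 0) NA_real_ else
    stats::t.test(d)$p.value
  list(intra_cv = mean(per_food$intra_cv), inter_cv = mean(per_food$inter_cv),
       p_value = p, per_food = per_food)
}
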