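# Meal scoring and menu construction/validation for the two diet arms.
#
# The MED arm is defined by macronutrient bounds; the PPT arm is defined by
# predictor-based meal scores: a meal's predicted PPGR is ranked within the
# person's own distribution of predictions over a meal bank and mapped to a
# 1 (best) .. 5 (worst) score.

#' Diet specification
#'
#' Macronutrient bounds (as % of energy) for a Mediterranean-style menu, or
#' the maximum allowed predictor meal score for a personalized
#' postprandial-targeting menu. MED defaults: 45-65% of energy from
#' carbohydrate and 15-20% from protein (inclusive ranges), under 35% from
#' fat and under 10% from saturated fat (strict upper bounds).
#'
#' @param name `"MED"` or `"PPT"`
#' @param carb_range,protein_range inclusive percentage-of-energy ranges
#' @param fat_max,satfat_max strict upper percentage-of-energy bounds
#' @param max_score maximum allowed meal score per slot (PPT only)
#' @return a list of class `diet_spec`
#' @export
diet_spec <- function(name = c("MED", "PPT"),
                      carb_range = c(45, 65), protein_range = c(15, 20),
                      fat_max = 35, satfat_max = 10, max_score = 2) {
  name <- match.arg(name)
  stopifnot(carb_range[1] <= carb_range[2], protein_range[1] <= protein_range[2],
            all(c(carb_range, protein_range, fat_max, satfat_max) >= 0),
            all(c(carb_range, protein_range, fat_max, satfat_max) <= 100),
            max_score %in% 1:5)
  structure(list(name = name, carb_range = carb_range,
                 protein_range = protein_range, fat_max = fat_max,
                 satfat_max = satfat_max, max_score = max_score),
            class = "diet_spec")
}

#' Assign a 1-5 meal score from a predicted PPGR
#'
#' Ranks a meal's predicted PPGR within the person's reference distribution
#' of predictions over a meal bank and returns the quantile bin: with the
#' default quintile cut-points, predictions at or below the person's 20th
#' percentile score 1 (best) and predictions above the 80th percentile score
#' 5 (worst). Ties take the lower score, so a degenerate reference (all
#' values identical) scores every meal 1. The cut-points are configurable
#' because the published scoring thresholds are not public; person-relative
#' quintiles are this package's documented convention.
#'
#' @param predicted_ppgr predicted PPGR(s), mg/dl x h
#' @param person_reference numeric vector of the person's predicted PPGRs
#'   over a reference meal bank (at least 5 values)
#' @param cut_points probabilities of the score-bin boundaries (default
#'   quintiles `c(0.2, 0.4, 0.6, 0.8)`)
#' @return integer score(s) in 1..5
#' @export
assign_meal_score <- function(predicted_ppgr, person_reference,
                              cut_points = c(0.2, 0.4, 0.6, 0.8)) {
  if (length(person_reference) == 0L) rlang::abort("empty reference distribution")
  if (length(person_reference) < 5L) {
    rlang::abort("reference distribution needs at least 5 values")
  }
  qs <- stats::quantile(person_reference, probs = cut_points, names = FALSE,
                        type = 7)
  vapply(predicted_ppgr, function(p) {
    1L + sum(p > qs) # ties (p == boundary) take the lower score
  }, integer(1))
}

#' Validate a menu against a diet's macronutrient bounds
#'
#' Computes energy-weighted macronutrient percentages over the whole
#' candidate pool of a menu (the designed menu, not a consumed subset) and
#' checks them against the spec: carbohydrate and protein must fall inside
#' their inclusive ranges; fat and saturated fat must stay strictly below
#' their bounds. Zero-kcal meals cannot contribute energy shares and are
#' excluded with a warning. Macronutrient energies use 4 kcal/g for
#' carbohydrate and protein and 9 kcal/g for fat.
#'
#' @param menu tibble of candidate meals with `kcal`, `carbs_g`, `protein_g`,
#'   `fat_g`, `satfat_g` (and optionally `slot`)
#' @param spec a [diet_spec()]
#' @return a list of class `menu_validation`: `valid` (logical),
#'   `percentages` (named numeric), `violations` (character vector naming
#'   each violated bound)
#' @export
validate_menu <- function(menu, spec = diet_spec("MED")) {
  zero <- menu$kcal <= 0
  if (any(zero)) {
    rlang::warn(sprintf("%d zero-kcal meal(s) excluded from menu validation", sum(zero)))
    menu <- menu[!zero, , drop = FALSE]
  }
  if (nrow(menu) == 0L || sum(menu$kcal) <= 0) {
    rlang::abort("menu has no energy to validate")
  }
  total <- sum(menu$kcal)
  pct <- c(
    carbohydrate = 100 * sum(menu$carbs_g) * 4 / total,
    protein = 100 * sum(menu$protein_g) * 4 / total,
    fat = 100 * sum(menu$fat_g) * 9 / total,
    saturated_fat = 100 * sum(menu$satfat_g) * 9 / total
  )
  violations <- character(0)
  if (pct[["carbohydrate"]] < spec$carb_range[1] ||
      pct[["carbohydrate"]] > spec$carb_range[2]) {
    violations <- c(violations, sprintf(
      "carbohydrate %.1f%% outside [%g, %g]%%", pct[["carbohydrate"]],
      spec$carb_range[1], spec$carb_range[2]))
  }
  if (pct[["protein"]] < spec$protein_range[1] ||
      pct[["protein"]] > spec$protein_range[2]) {
    violations <- c(violations, sprintf(
      "protein %.1f%% outside [%g, %g]%%", pct[["protein"]],
      spec$protein_range[1], spec$protein_range[2]))
  }
  if (pct[["fat"]] >= spec$fat_max) {
    violations <- c(violations, sprintf("fat %.1f%% not < %g%%",
                                        pct[["fat"]], spec$fat_max))
  }
  if (pct[["saturated_fat"]] >= spec$satfat_max) {
    violations <- c(violations, sprintf("saturated fat %.1f%% not < %g%%",
                                        pct[["saturated_fat"]], spec$satfat_max))
  }
  structure(list(valid = length(violations) == 0L, percentages = pct,
                 violations = violations),
            class = "menu_validation")
}

#' @export
print.menu_validation <- function(x, ...) {
  cat(sprintf("<menu_validation> %s\n", if (x$valid) "valid" else "INVALID"))
  cat(sprintf("  energy shares: %s\n",
              paste(sprintf("%s %.1f%%", names(x$percentages), x$percentages),
                    collapse = ", ")))
  for (v in x$violations) cat("  violated:", v, "\n")
  invisible(x)
}

#' Dominant food of a meal
#'
#' Returns the single food contributing strictly more than `threshold`
#' (default 70%) of the meal's energy, or `NA` when no food does. Used to
#' match meals across persons for the intra- vs inter-person variability
#' analysis. A foods list whose energies exceed the meal total by more than
#' 10% indicates inconsistent logging and is an error.
#'
#' @param foods tibble of meal components with `name` and `kcal`
#' @param meal_kcal total meal energy, kcal
#' @param threshold dominance threshold as a fraction of meal energy
#' @return food name, or `NA_character_`
#' @export
dominant_food <- function(foods, meal_kcal, threshold = 0.70) {
  if (is.null(foods) || nrow(foods) == 0L) rlang::abort("foods list is empty")
  if (sum(foods$kcal) > meal_kcal * 1.10) {
    rlang::abort("food energies exceed meal energy by more than 10%")
  }
  shares <- foods$kcal / meal_kcal
  i <- which.max(shares)
  if (shares[i] > threshold) foods$name[i] else NA_character_
}

#' Build a personalized postprandial-targeting menu
#'
#' Fills each menu slot with its lowest-scoring candidate meals: only
#' candidates whose meal score is at most `max_score` qualify, and within a
#' slot candidates are ranked by score, then by lower predicted PPGR, then
#' by meal name (lexicographic) so the selection is deterministic. A slot
#' with fewer qualifying candidates than requested is an error naming the
#' slot.
#'
#' @param candidates tibble of candidate meals with `meal`, `slot`,
#'   `predicted_ppgr` columns
#' @param person_reference reference distribution for [assign_meal_score()]
#' @param max_score maximum admissible meal score (default 2)
#' @param slot_counts named integer vector of meals wanted per slot
#'   (default 4 each for breakfast/lunch/dinner, 10 for snack)
#' @param cut_points score-bin boundaries passed to [assign_meal_score()]
#' @return `candidates` subset forming the menu, with a `meal_score` column
#' @export
build_ppt_menu <- function(candidates, person_reference, max_score = 2,
                           slot_counts = c(breakfast = 4, lunch = 4,
                                           dinner = 4, snack = 10),
                           cut_points = c(0.2, 0.4, 0.6, 0.8)) {
  candidates$meal_score <- assign_meal_score(candidates$predicted_ppgr,
                                             person_reference, cut_points)
  picked <- lapply(names(slot_counts), function(slot) {
    pool <- candidates[candidates$slot == slot &
                         candidates$meal_score <= max_score, , drop = FALSE]
    want <- slot_counts[[slot]]
    if (nrow(pool) < want) {
      rlang::abort(sprintf(
        "slot '%s' has only %d candidate(s) with score <= %d (need %d)",
        slot, nrow(pool), max_score, want))
    }
    pool <- pool[order(pool$meal_score, pool$predicted_ppgr, pool$meal), ,
                 drop = FALSE]
    utils::head(pool, want)
  })
  dplyr::bind_rows(picked)
}
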