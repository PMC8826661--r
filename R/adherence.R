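# Diet-adherence grading: a composition grade that rewards sticking to
# predictor-based meal scores, a calorie grade that rewards sticking to the
# prescribed caloric target, and the 2-week feedback report combining both.

#' Adherence grading configuration
#'
#' Bundles the tunables of the adherence grading system: the caloric target,
#' the per-meal energy trim interval used for calorie-weighting, the minimum
#' total logged energy below which no composition grade is computed, the
#' meal-score-to-grade map (score 1, the best meal for that person, earns
#' grade 100; score 5 earns 0), and the two knots of the linear calorie
#' penalty (full credit within 15% deviation from the target, zero credit at
#' or beyond 60%).
#'
#' @param caloric_target prescribed daily energy target, kcal/day
#' @param trim_interval two-element numeric: per-meal kcal is clamped into
#'   this interval before weighting (default `c(100, 500)`)
#' @param min_logged_kcal minimum untrimmed total kcal logged in the period
#'   for a composition grade to be computed (default 100)
#' @param grade_map named numeric mapping meal scores "1".."5" to grades
#' @param penalty_knots two-element numeric: deviation fractions at which
#'   the calorie grade is 100 and 0 (default `c(0.15, 0.60)`)
#' @return a list of class `adherence_config`
#' @export
adherence_config <- function(caloric_target = 2000,
                             trim_interval = c(100, 500),
                             min_logged_kcal = 100,
                             grade_map = c("1" = 100, "2" = 80, "3" = 50,
                                           "4" = 25, "5" = 0),
                             penalty_knots = c(0.15, 0.60)) {
  stopifnot(
    caloric_target > 0,
    length(trim_interval) == 2L, trim_interval[1] <= trim_interval[2],
    length(grade_map) == 5L,
    all(grade_map >= 0 & grade_map <= 100),
    all(diff(grade_map) <= 0), # grade non-increasing in meal score
    length(penalty_knots) == 2L, penalty_knots[1] < penalty_knots[2]
  )
  structure(
    list(caloric_target = caloric_target, trim_interval = trim_interval,
         min_logged_kcal = min_logged_kcal, grade_map = grade_map,
         penalty_knots = penalty_knots),
    class = "adherence_config"
  )
}

#' Grade of a single meal score
#'
#' Table lookup in the configured score-to-grade map: score 1 -> 100,
#' 2 -> 80, 3 -> 50, 4 -> 25, 5 -> 0 by default.
#'
#' @param score integer meal score(s) in 1..5
#' @param config an [adherence_config()]
#' @return numeric grade(s) in \[0, 100\]
#' @export
meal_grade <- function(score, config = adherence_config()) {
  if (any(is.na(score)) || !all(score %in% 1:5)) {
    rlang::abort("meal score must be in {1..5}")
  }
  unname(config$grade_map[as.character(score)])
}

#' Calorie-weighted diet-composition grade for a period
#'
#' Each logged meal's score grade is weighted by its energy, with the energy
#' first clamped into the trim interval (a 1000-kcal meal counts as 500, an
#' 80-kcal snack as 100) so that no single meal dominates the period grade.
#' If the untrimmed total energy logged over the period falls below
#' `min_logged_kcal`, too little was logged to grade and `NA` is returned.
#' Meals without a score cannot be graded and are excluded with a warning.
#'
#' @param meals meal-event tibble with `kcal` and `meal_score`
#' @param config an [adherence_config()]
#' @return grade in \[0, 100\], or `NA` when too little energy was logged
#' @export
composition_grade <- function(meals, config = adherence_config()) {
  if (nrow(meals) == 0L) return(NA_real_)
  unscored <- is.na(meals$meal_score)
  if (any(unscored)) {
    rlang::warn(sprintf("%d meal(s) without a meal score excluded from composition grade",
                        sum(unscored)))
    meals <- meals[!unscored, ]
  }
  if (nrow(meals) == 0L) return(NA_real_)
  if (sum(meals$kcal) < config$min_logged_kcal) return(NA_real_)
  w <- pmin(pmax(meals$kcal, config$trim_interval[1]), config$trim_interval[2])
  g <- meal_grade(meals$meal_score, config)
  sum(w * g) / sum(w)
}

#' Calorie-intake adherence grade
#'
#' Grades how close the period's mean daily energy intake is to the caloric
#' target CT. With deviation d = |intake - CT| / CT, the grade is 100 for
#' d <= 0.15, 0 for d >= 0.60, and interpolates linearly in between:
#' 100 (0.60 - d) / (0.60 - 0.15). The deviation is symmetric: over- and
#' under-eating relative to target are penalized alike.
#'
#' @param intake mean daily energy intake over the period, kcal/day
#' @param config an [adherence_config()] (supplies CT and the penalty knots)
#' @return grade in \[0, 100\]
#' @export
calorie_grade <- function(intake, config = adherence_config()) {
  if (any(intake < 0)) rlang::abort("intake must be non-negative")
  ct <- config$caloric_target
  k <- config$penalty_knots
  d <- abs(intake - ct) / ct
  ifelse(d <= k[1], 100,
         ifelse(d >= k[2], 0, 100 * (k[2] - d) / (k[2] - k[1])))
}

#' Two-week feedback report
#'
#' The periodic report sent to a participant: the composition grade, the
#' calorie grade (computed on the period's mean daily intake), and the k
#' "best" (lowest-score) and "worst" (highest-score) logged meals. Ties in
#' score are broken toward the smaller meal on the best list and the larger
#' meal on the worst list, so the lists highlight the most consequential
#' choices.
#'
#' @param meals meal-event tibble for one 2-week period (needs `time`,
#'   `kcal`, `meal_score`)
#' @param config an [adherence_config()]
#' @param k number of meals on each list (default 5)
#' @param days number of days in the period, used to turn total logged
#'   energy into a mean daily intake (default 14)
#' @return a list of class `adherence_report` with elements
#'   `composition_grade`, `calorie_grade`, `best_meals`, `worst_meals`
#' @export
feedback_report <- function(meals, config = adherence_config(), k = 5,
                            days = 14) {
  scored <- meals[!is.na(meals$meal_score), , drop = FALSE]
  comp <- suppressWarnings(composition_grade(meals, config))
  cal <- if (nrow(meals) > 0L) calorie_grade(sum(meals$kcal) / days, config)
         else NA_real_
  best <- scored[order(scored$meal_score, scored$kcal), , drop = FALSE]
  worst <- scored[order(-scored$meal_score, -scored$kcal), , drop = FALSE]
  structure(
    list(composition_grade = comp, calorie_grade = cal,
         best_meals = utils::head(best, k), worst_meals = utils::head(worst, k)),
    class = "adherence_report"
  )
}

#' @export
print.adherence_report <- function(x, ...) {
  fmt <- function(g) if (is.na(g)) "not computed" else sprintf("%.1f", g)
  cat(sprintf("<adherence_report> composition %s, calories %s; %d best / %d worst meals listed\n",
              fmt(x$composition_grade), fmt(x$calorie_grade),
              nrow(x$best_meals), nrow(x$worst_meals)))
  invisible(x)
}

#' Mean feedback grade per participant
#'
#' Averages the composition grades of a participant's period reports
#' (unweighted over periods). Participants whose reports all lack a
#' composition grade are dropped. This per-participant mean is what the
#' adherence median-split analysis of the 6-month intervention uses.
#'
#' @param reports tibble with `participant_id` and `composition_grade`
#'   (one row per participant x period)
#' @return tibble with `participant_id`, `mean_grade`
#' @export
mean_feedback_grade <- function(reports) {
  reports |>
    dplyr::filter(!is.na(.data$composition_grade)) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(mean_grade = mean(.data$composition_grade),
                     .groups = "drop")
}
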