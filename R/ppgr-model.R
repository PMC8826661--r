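# Pluggable PPGR prediction and leave-one-person-out evaluation.
#
# Two predictors are provided behind one interface: a carbohydrate-counting
# baseline (univariate least squares of iAUC on carbohydrate grams) and a
# feature-based surrogate, a gradient-boosted ensemble of shallow regression
# trees over meal macronutrients, clinical measures and selected taxa
# abundances. A fit procedure is any function(data) returning an object with
# a predict method; lopo_evaluate() holds out one person at a time.

#' Carbohydrate-counting baseline predictor
#'
#' Fits the standard clinical baseline: ordinary least squares of measured
#' meal iAUC on the meal's carbohydrate content alone.
#'
#' @param data tibble with `carbs_g` and `iauc` columns (one row per meal)
#' @return an object of class `carb_baseline` with a [predict()] method
#' @export
carb_baseline_fit <- function(data) {
  data <- data[!is.na(data$carbs_g) & !is.na(data$iauc), , drop = FALSE]
  if (nrow(data) < 2L || length(unique(data$carbs_g)) < 2L) {
    rlang::abort("carbohydrate baseline needs >= 2 meals with distinct carbohydrate values")
  }
  fit <- stats::lm(iauc ~ carbs_g, data = data)
  structure(list(fit = fit, coef = stats::coef(fit)), class = "carb_baseline")
}

#' @export
predict.carb_baseline <- function(object, newdata, ...) {
  unname(stats::predict(object$fit, newdata = newdata))
}

#' Feature-based PPGR surrogate predictor
#'
#' A gradient-boosted ensemble of shallow regression trees mapping a meal
#' feature vector (macronutrients plus the person's clinical and microbiome
#' features) to predicted iAUC. Hyperparameters are fixed: 200 trees of
#' depth 3, learning rate 0.05, 80% row subsampling; the fit is
#' deterministic given `seed` (single-threaded). Negative predictions are
#' clipped to zero since an incremental AUC is non-negative. Feature columns
#' are every numeric column of `data` except `iauc` and identifiers.
#'
#' @param data tibble with an `iauc` response column, a `participant_id`
#'   column, and numeric feature columns; at least `min_rows` complete rows
#' @param nrounds,max_depth,eta,subsample boosting hyperparameters
#' @param min_rows minimum number of training meals (default 50)
#' @param seed integer seed controlling row subsampling
#' @return an object of class `ppgr_surrogate` with a [predict()] method
#' @export
feature_model_fit <- function(data, nrounds = 200, max_depth = 3, eta = 0.05,
                              subsample = 0.8, min_rows = 50, seed = 1) {
  feats <- feature_columns(data)
  keep <- stats::complete.cases(data[, c(feats, "iauc")])
  data <- data[keep, , drop = FALSE]
  if (nrow(data) < min_rows) {
    rlang::abort(sprintf("surrogate needs >= %d complete training meals, got %d",
                         min_rows, nrow(data)))
  }
  x <- as.matrix(data[, feats, drop = FALSE])
  booster <- xgboost::xgboost(
    x, data$iauc,
    objective = "reg:squarederror",
    nrounds = nrounds, max_depth = max_depth, learning_rate = eta,
    subsample = subsample, nthreads = 1, seed = seed, verbosity = 0
  )
  structure(list(booster = booster, features = feats), class = "ppgr_surrogate")
}

feature_columns <- function(data) {
  drop <- c("iauc", "participant_id", "meal", "time", "slot")
  feats <- setdiff(names(data), drop)
  feats[vapply(data[feats], is.numeric, logical(1))]
}

#' @export
predict.ppgr_surrogate <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  pmax(stats::predict(object$booster, x), 0)
}

#' Leave-one-person-out evaluation of a PPGR predictor
#'
#' For each person in turn, fits the supplied procedure on every other
#' person's meals and predicts the held-out person's meals; predictions are
#' pooled over persons and compared with measurements. Explained variance is
#' reported as 100 times the squared pooled Pearson correlation between
#' predicted and measured iAUC (the predicted-vs-measured dot-cloud
#' convention); `r2_form = "ss"` switches to the 1 - SSE/SST form. A
#' constant prediction vector has no defined correlation and is reported as
#' 0% explained variance. Persons with no meals are skipped with a warning.
#'
#' @param data tibble with `participant_id`, `iauc` and feature columns
#' @param fit_fun function(training_data) returning either an object with a
#'   `predict(object, newdata)` method or a plain `function(newdata)`
#'   prediction function
#' @param r2_form `"cor"` (default, squared Pearson r) or `"ss"`
#'   (1 - SSE/SST)
#' @return a list of class `ppgr_evaluation`: `per_meal` tibble
#'   (`participant_id`, `measured`, `predicted`), `explained_variance_pct`,
#'   `correlation`, `per_person` tibble of per-person correlations, and
#'   `fold_training_ids` (list of the participant ids trained on per fold,
#'   for audit)
#' @export
lopo_evaluate <- function(data, fit_fun, r2_form = c("cor", "ss")) {
  r2_form <- match.arg(r2_form)
  persons <- unique(data$participant_id)
  if (length(persons) < 2L) rlang::abort("leave-one-person-out needs >= 2 persons")
  rows <- list()
  fold_ids <- list()
  for (p in persons) {
    test <- data[data$participant_id == p, , drop = FALSE]
    train <- data[data$participant_id != p, , drop = FALSE]
    if (nrow(test) == 0L) {
      rlang::warn(sprintf("person '%s' has no meals; skipped", p))
      next
    }
    model <- fit_fun(train)
    preds <- if (is.function(model)) model(test) else stats::predict(model, test)
    rows[[p]] <- tibble::tibble(
      participant_id = p,
      measured = test$iauc,
      predicted = as.numeric(preds)
    )
    fold_ids[[p]] <- unique(train$participant_id)
  }
  per_meal <- dplyr::bind_rows(rows)
  structure(
    c(evaluate_predictions(per_meal, r2_form),
      list(fold_training_ids = fold_ids)),
    class = "ppgr_evaluation"
  )
}

#' Summarize pooled predicted-vs-measured agreement
#'
#' @param per_meal tibble with `participant_id`, `measured`, `predicted`
#' @param r2_form `"cor"` or `"ss"` (see [lopo_evaluate()])
#' @return list with `per_meal`, `explained_variance_pct`, `correlation`,
#'   `per_person`
#' @export
evaluate_predictions <- function(per_meal, r2_form = c("cor", "ss")) {
  r2_form <- match.arg(r2_form)
  r <- if (stats::sd(per_meal$predicted) == 0 ||
           stats::sd(per_meal$measured) == 0) NA_real_ else
    stats::cor(per_meal$predicted, per_meal$measured)
  ev <- switch(r2_form,
    cor = if (is.na(r)) 0 else 100 * r^2,
    ss = {
      sst <- sum((per_meal$measured - mean(per_meal$measured))^2)
      if (sst == 0) 0 else
        100 * (1 - sum((per_meal$measured - per_meal$predicted)^2) / sst)
    }
  )
  per_person <- per_meal |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      correlation = if (dplyr::n() >= 3 && stats::sd(.data$predicted) > 0 &&
                        stats::sd(.data$measured) > 0)
        stats::cor(.data$predicted, .data$measured) else NA_real_,
      .groups = "drop"
    )
  list(per_meal = per_meal, explained_variance_pct = ev,
       correlation = r, per_person = per_person)
}

#' @export
print.ppgr_evaluation <- function(x, ...) {
  cat(sprintf(
    "<ppgr_evaluation> %d meals, %d persons; explained variance %.1f%%\n",
    nrow(x$per_meal), length(unique(x$per_meal$participant_id)),
    x$explained_variance_pct))
  invisible(x)
}
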