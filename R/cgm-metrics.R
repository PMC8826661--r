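# CGM-derived glycemic measures.
#
# All metrics operate on a single participant's trace; `glycemic_summary()`
# maps them over a multi-participant trace. Times are handled in hours so
# every area is in mg/dl x h.

single_participant <- function(trace) {
  ids <- unique(trace$participant_id)
  if (length(ids) > 1L) {
    rlang::abort("this metric expects a single participant's trace; use glycemic_summary() for cohorts")
  }
  trace
}

#' Postprandial glucose response (2-h incremental AUC) of one meal
#'
#' Quantifies the glucose excursion after a meal as the incremental area
#' under the CGM curve in the `window_hours` after the meal was logged, in
#' mg/dl x h. The baseline is the glucose at the meal-log time, obtained by
#' linear interpolation between the neighbouring readings. Area below the
#' baseline contributes zero under the default incremental-AUC convention
#' (`clip_below_baseline = TRUE`); setting it to `FALSE` yields the signed
#' "net AUC" for sensitivity analyses.
#'
#' A meal is computable only when at least two readings fall inside the
#' window, the baseline is interpolable, and the assembled curve covers at
#' least `min_coverage` of the window; otherwise the result is flagged
#' uncomputable and carries `NA` values.
#'
#' @param trace single-participant `cgm_trace`
#' @param meal_time POSIXct meal-log time
#' @param window_hours post-meal window length in hours (default 2)
#' @param min_coverage minimum fraction of the window the readings must span
#'   (default 0.75)
#' @param clip_below_baseline clip area below baseline to zero (default TRUE)
#' @return a one-row tibble with `iauc` (mg/dl x h), `baseline` (mg/dl),
#'   `coverage` (fraction of window) and `computable` (logical)
#' @export
meal_ppgr <- function(trace, meal_time, window_hours = 2,
                      min_coverage = 0.75, clip_below_baseline = TRUE) {
  trace <- single_participant(trace)
  t0 <- as.numeric(meal_time)
  t_end <- t0 + window_hours * 3600
  tt <- as.numeric(trace$time)
  gg <- trace$glucose

  uncomputable <- tibble::tibble(iauc = NA_real_, baseline = NA_real_,
                                 coverage = NA_real_, computable = FALSE)
  inside <- which(tt >= t0 & tt <= t_end)
  if (length(inside) < 2L) return(uncomputable)

  baseline <- interp_at(tt, gg, t0)
  if (is.na(baseline)) return(uncomputable)

  times <- tt[inside]
  vals <- gg[inside]
  if (times[1] > t0) {
    times <- c(t0, times); vals <- c(baseline, vals)
  }
  if (times[length(times)] < t_end) {
    g_end <- interp_at(tt, gg, t_end)
    if (!is.na(g_end)) {
      times <- c(times, t_end); vals <- c(vals, g_end)
    }
  }
  coverage <- (times[length(times)] - times[1]) / (window_hours * 3600)
  if (coverage < min_coverage) {
    return(tibble::tibble(iauc = NA_real_, baseline = baseline,
                          coverage = coverage, computable = FALSE))
  }
  hours <- (times - t0) / 3600
  excess <- vals - baseline
  iauc <- if (clip_below_baseline) trapz_pos(hours, excess) else trapz(hours, excess)
  tibble::tibble(iauc = iauc, baseline = baseline,
                 coverage = coverage, computable = TRUE)
}

#' Per-meal PPGR table for a meal log
#'
#' Applies [meal_ppgr()] to every logged meal, matching meals to traces by
#' participant. Uncomputable meals (insufficient CGM coverage of the post-meal
#' window) are kept in the table, flagged, and counted in a message.
#'
#' @param traces `cgm_trace` covering the logged participants
#' @param meals meal-event tibble (see [read_meal_log()])
#' @inheritParams meal_ppgr
#' @return `meals` with `iauc`, `baseline`, `coverage`, `computable` columns
#' @export
ppgr_table <- function(traces, meals, window_hours = 2, min_coverage = 0.75,
                       clip_below_baseline = TRUE) {
  split_traces <- split(tibble::as_tibble(traces), traces$participant_id)
  res <- purrr::map(seq_len(nrow(meals)), function(i) {
    tr <- split_traces[[meals$participant_id[i]]]
    if (is.null(tr)) {
      return(tibble::tibble(iauc = NA_real_, baseline = NA_real_,
                            coverage = NA_real_, computable = FALSE))
    }
    meal_ppgr(tr, meals$time[i], window_hours = window_hours,
              min_coverage = min_coverage,
              clip_below_baseline = clip_below_baseline)
  })
  out <- dplyr::bind_cols(meals, dplyr::bind_rows(res))
  n_bad <- sum(!out$computable)
  if (n_bad > 0L) {
    rlang::inform(sprintf("%d meal(s) uncomputable (insufficient CGM coverage); excluded from summaries", n_bad))
  }
  out
}

#' Averaged PPGR over consecutive blocks of readings
#'
#' The connection-wide analogue of the meal PPGR: each sensor connection is
#' partitioned into consecutive non-overlapping blocks of `block` readings
#' (9 readings at the nominal 15-minute cadence span about two hours), the
#' incremental AUC of each block is computed with the block's first reading
#' as baseline (below-baseline area clipped), and the mean over all complete
#' blocks is returned. A trailing remainder shorter than `block` is
#' discarded; blocks never straddle connections. With `sliding = TRUE` every
#' window of `block` consecutive readings within a connection is used
#' instead of disjoint blocks.
#'
#' @param trace single-participant `cgm_trace`
#' @param block readings per block (default 9)
#' @param sliding use overlapping sliding windows instead of disjoint blocks
#' @param clip_below_baseline clip area below the block baseline (default TRUE)
#' @return mean block iAUC in mg/dl x h, or `NA` if no connection holds a
#'   complete block
#' @export
averaged_ppgr <- function(trace, block = 9, sliding = FALSE,
                          clip_below_baseline = TRUE) {
  trace <- single_participant(trace)
  block_iaucs <- unlist(lapply(split(seq_len(nrow(trace)), trace$connection),
    function(idx) {
      n <- length(idx)
      if (n < block) return(numeric(0))
      starts <- if (sliding) seq_len(n - block + 1L) else
        seq(1L, n - block + 1L, by = block)
      vapply(starts, function(s) {
        rows <- idx[s:(s + block - 1L)]
        hours <- as.numeric(trace$time[rows] - trace$time[rows[1]], units = "hours")
        excess <- trace$glucose[rows] - trace$glucose[rows[1]]
        if (clip_below_baseline) trapz_pos(hours, excess) else trapz(hours, excess)
      }, numeric(1))
    }))
  if (length(block_iaucs) == 0L) return(NA_real_)
  mean(block_iaucs)
}

#' Glucose coefficient of variation
#'
#' Glucose fluctuations measured as the ratio between the standard deviation
#' and the mean of all readings in the period (sample SD).
#'
#' @param trace single-participant `cgm_trace`
#' @param from,to optional POSIXct bounds restricting the period (inclusive)
#' @return sd/mean, or `NA` with fewer than 2 readings in the period
#' @export
glucose_cv <- function(trace, from = NULL, to = NULL) {
  trace <- single_participant(trace)
  keep <- rep(TRUE, nrow(trace))
  if (!is.null(from)) keep <- keep & trace$time >= from
  if (!is.null(to)) keep <- keep & trace$time <= to
  g <- trace$glucose[keep]
  cv_of(g)
}

# time with y > thr within a linear segment of duration d (strictly-above)
segment_time_above <- function(y1, y2, d, thr) {
  if (y1 > thr && y2 > thr) return(d)
  if (y1 <= thr && y2 <= thr) return(0)
  if (y1 > thr) d * (y1 - thr) / (y1 - y2) else d * (y2 - thr) / (y2 - y1)
}

#' Daily hours above glycemic thresholds
#'
#' Daily duration (hours/day) of glucose levels strictly above each
#' threshold. Between consecutive readings of the same connection the trace
#' is taken as linear, so the crossing time at a threshold is resolved
#' exactly; segments crossing local midnight are split so each calendar day
#' accrues only its own time. A day qualifies when it holds at least
#' `min_daily_readings` readings (default 48, half the nominal 96/day), a
#' guard against sensor-swap days biasing the average. Within each
#' qualifying day the above-threshold time is scaled to a 24-h day by the
#' observed (covered) time, and the returned value is the mean over
#' qualifying days.
#'
#' @param trace single-participant `cgm_trace`
#' @param thresholds glucose thresholds in mg/dl
#' @param min_daily_readings minimum readings for a day to qualify
#' @return named numeric vector of hours/day per threshold, or `NA`s when no
#'   day qualifies
#' @export
time_above <- function(trace, thresholds = c(140, 150, 160, 170, 180),
                       min_daily_readings = 48) {
  trace <- single_participant(trace)
  out <- stats::setNames(rep(NA_real_, length(thresholds)),
                         as.character(thresholds))
  if (nrow(trace) < 2L) return(out)

  tt <- as.numeric(trace$time)
  gg <- trace$glucose
  same_conn <- trace$connection[-1] == trace$connection[-nrow(trace)]

  day_of <- function(t) as.Date(as.POSIXct(t, origin = "1970-01-01", tz = "UTC"),
                                tz = "UTC")
  # accumulators keyed by day string
  observed <- list()
  above <- list()
  add <- function(day, dt_hours, above_hours) {
    key <- as.character(day)
    observed[[key]] <<- (observed[[key]] %||% 0) + dt_hours
    above[[key]] <<- (above[[key]] %||% rep(0, length(thresholds))) + above_hours
  }

  for (i in which(same_conn)) {
    t1 <- tt[i]; t2 <- tt[i + 1L]
    if (t2 <= t1) next
    y1 <- gg[i]; y2 <- gg[i + 1L]
    # split [t1, t2] at UTC midnights
    first_cut <- floor(t1 / 86400) * 86400 + 86400
    cuts <- if (first_cut < t2) seq(first_cut, t2 - 1e-9, by = 86400) else numeric(0)
    cuts <- cuts[cuts > t1 & cuts < t2]
    bounds <- c(t1, cuts, t2)
    for (j in seq_len(length(bounds) - 1L)) {
      a <- bounds[j]; b <- bounds[j + 1L]
      ya <- y1 + (y2 - y1) * (a - t1) / (t2 - t1)
      yb <- y1 + (y2 - y1) * (b - t1) / (t2 - t1)
      d <- (b - a) / 3600
      ab <- vapply(thresholds, function(thr) segment_time_above(ya, yb, d, thr),
                   numeric(1))
      add(day_of(a), d, ab)
    }
  }

  counts <- table(as.character(day_of(tt)))
  qualifying <- names(counts)[counts >= min_daily_readings]
  qualifying <- qualifying[qualifying %in% names(observed)]
  if (length(qualifying) == 0L) return(out)

  per_day <- vapply(qualifying, function(key) {
    24 * above[[key]] / observed[[key]]
  }, numeric(length(thresholds)))
  per_day <- matrix(per_day, nrow = length(thresholds))
  stats::setNames(rowMeans(per_day), as.character(thresholds))
}

#' Mean PPGR by hour of day
#'
#' Buckets computable meals by the local hour of the meal timestamp and
#' averages their iAUC per bucket, mirroring an average-PPGR-through-the-day
#' profile. Hours without meals are absent from the result.
#'
#' @param ppgrs per-meal table from [ppgr_table()] (needs `time`, `iauc`,
#'   `computable`)
#' @return tibble with `hour` (0-23), `mean_ppgr`, `n`
#' @export
hourly_ppgr_profile <- function(ppgrs) {
  ppgrs |>
    dplyr::filter(.data$computable) |>
    dplyr::mutate(hour = as.integer(format(.data$time, "%H", tz = "UTC"))) |>
    dplyr::group_by(.data$hour) |>
    dplyr::summarise(mean_ppgr = mean(.data$iauc), n = dplyr::n(),
                     .groups = "drop")
}

#' Empirical percentiles of PPGR values
#'
#' Linear-interpolation empirical percentiles (R's default quantile
#' definition, type 7) of a set of meal iAUCs.
#'
#' @param values numeric iAUC values
#' @param percentiles percentile points in \[0, 100\]
#' @return named numeric vector, or `NA`s when `values` is empty
#' @export
ppgr_percentiles <- function(values, percentiles = c(10, 25, 50, 75, 90)) {
  values <- values[!is.na(values)]
  nm <- as.character(percentiles)
  if (length(values) == 0L) {
    return(stats::setNames(rep(NA_real_, length(percentiles)), nm))
  }
  stats::setNames(stats::quantile(values, probs = percentiles / 100,
                                  names = FALSE, type = 7), nm)
}

#' Per-participant glycemic summary
#'
#' One row per participant with the full set of CGM measures: mean glucose,
#' coefficient of variation, daily hours above each threshold, block-wise
#' averaged PPGR, and the mean and count of computable meal PPGRs.
#'
#' @param traces `cgm_trace` for one or more participants
#' @param meals meal-event tibble (optional; meal-based columns are `NA`
#'   without it)
#' @param thresholds thresholds passed to [time_above()]
#' @inheritParams meal_ppgr
#' @return a tibble, one row per participant
#' @export
glycemic_summary <- function(traces, meals = NULL,
                             thresholds = c(140, 150, 160, 170, 180),
                             window_hours = 2, min_coverage = 0.75) {
  ppgrs <- if (!is.null(meals) && nrow(meals) > 0L) {
    suppressMessages(ppgr_table(traces, meals, window_hours = window_hours,
                                min_coverage = min_coverage))
  } else NULL
  purrr::map_dfr(split(tibble::as_tibble(traces), traces$participant_id),
    function(tr) {
      tr <- as_cgm_trace(tr)
      ta <- time_above(tr, thresholds = thresholds)
      row <- tibble::tibble(
        participant_id = tr$participant_id[1],
        mean_glucose = mean(tr$glucose),
        glucose_cv = cv_of(tr$glucose),
        averaged_ppgr = averaged_ppgr(tr)
      )
      for (k in seq_along(thresholds)) {
        row[[paste0("hours_above_", thresholds[k])]] <- ta[[k]]
      }
      if (!is.null(ppgrs)) {
        mine <- ppgrs[ppgrs$participant_id == tr$participant_id[1], ]
        row$mean_meal_ppgr <- if (any(mine$computable))
          mean(mine$iauc[mine$computable]) else NA_real_
        row$n_meals <- nrow(mine)
        row$n_meals_uncomputable <- sum(!mine$computable)
      }
      row
    })
}
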