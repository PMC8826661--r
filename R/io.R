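# Readers and writers for the pipeline's tabular formats.
#
# All tabular I/O is UTF-8 delimited text with a header row. Timestamps are
# stored timezone-naive (parsed as UTC) so that calendar days split at local
# midnight, matching the day-level definition of all daily glycemic metrics.

GLUCOSE_RANGE <- c(20, 600) # physiologically plausible CGM range, mg/dl

#' Read a CGM trace file
#'
#' Reads a delimited file of continuous glucose monitoring readings with
#' columns `participant_id`, `time` (ISO 8601), `glucose` (mg/dl) and an
#' optional `connection` column identifying sensor wear periods. When no
#' connection column is present, connections are inferred from gaps longer
#' than `gap_hours` between consecutive readings: the nominal 15-minute
#' sampling cadence of the sensor makes multi-hour gaps unambiguous wear
#' breaks (sensor replaced every two weeks, or detached).
#'
#' Rows with glucose outside the plausible \[20, 600\] mg/dl sensor range are
#' rejected with a warning stating how many were dropped; an unparseable
#' timestamp is a hard error naming the offending row.
#'
#' @param path path to a delimited text file
#' @param delim field delimiter (default `","`)
#' @param gap_hours gap between consecutive readings (hours) that starts a
#'   new connection when the file carries no `connection` column; default 3
#' @return a `cgm_trace` tibble with columns `participant_id`, `time`
#'   (POSIXct), `glucose`, `connection`, sorted by time within participant
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "participant_id,time,glucose",
#'   "P01,2021-01-01 08:00:00,110",
#'   "P01,2021-01-01 08:15:00,118"
#' ), path)
#' read_cgm(path)
read_cgm <- function(path, delim = ",", gap_hours = 3) {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  assert_cols(raw, c("participant_id", "time", "glucose"), "CGM file")
  time <- parse_timestamps(raw$time)
  bad_time <- which(is.na(time))
  if (length(bad_time) > 0L) {
    rlang::abort(sprintf("unparseable timestamp in row %d: '%s'",
                         bad_time[1], raw$time[bad_time[1]]))
  }
  glucose <- as.numeric(raw$glucose)
  out_of_range <- is.na(glucose) | glucose < GLUCOSE_RANGE[1] | glucose > GLUCOSE_RANGE[2]
  if (any(out_of_range)) {
    rlang::warn(sprintf("rejected %d reading(s) with glucose outside [%g, %g] mg/dl",
                        sum(out_of_range), GLUCOSE_RANGE[1], GLUCOSE_RANGE[2]))
  }
  df <- tibble::tibble(
    participant_id = raw$participant_id,
    time = time,
    glucose = glucose,
    connection = if ("connection" %in% names(raw)) as.integer(raw$connection) else NA_integer_
  )[!out_of_range, ]
  as_cgm_trace(df, gap_hours = gap_hours)
}

# ISO 8601-ish timestamp parsing that yields NA (not an error) on failure,
# so callers can report the offending row
parse_timestamps <- function(x) {
  formats <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
               "%Y-%m-%d %H:%M", "%Y-%m-%d")
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in formats) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(x[todo], fmt, tz = "UTC"), tz = "UTC")
  }
  out
}

#' Coerce a data frame of readings to a `cgm_trace`
#'
#' Sorts readings by time within participant and, when the `connection`
#' column is absent or all-missing, infers connections from inter-reading
#' gaps exceeding `gap_hours`.
#'
#' @param df data frame with `participant_id`, `time`, `glucose` and
#'   optionally `connection`
#' @inheritParams read_cgm
#' @return a `cgm_trace` tibble
#' @export
as_cgm_trace <- function(df, gap_hours = 3) {
  assert_cols(df, c("participant_id", "time", "glucose"), "CGM data")
  df <- tibble::as_tibble(df)
  if (!inherits(df$time, "POSIXct")) df$time <- as.POSIXct(df$time, tz = "UTC")
  df <- dplyr::arrange(df, .data$participant_id, .data$time)
  if (!"connection" %in% names(df) || all(is.na(df$connection))) {
    df <- df |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::mutate(
        connection = cumsum(c(
          1L,
          as.numeric(diff(.data$time), units = "hours") > gap_hours
        ))
      ) |>
      dplyr::ungroup()
  }
  df$connection <- as.integer(df$connection)
  stopifnot(all(df$glucose >= GLUCOSE_RANGE[1] & df$glucose <= GLUCOSE_RANGE[2]))
  class(df) <- c("cgm_trace", class(tibble::tibble()))
  df
}

#' Write a CGM trace to CSV
#' @param trace a `cgm_trace` tibble
#' @param path output path
#' @return `path`, invisibly
#' @export
write_cgm <- function(trace, path) {
  out <- tibble::as_tibble(trace)
  out$time <- format(out$time, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a meal log
#'
#' Reads a delimited meal log with columns `participant_id`, `time`, `meal`,
#' `kcal`, `carbs_g`, `protein_g`, `fat_g`, `satfat_g`, and optional columns
#' `meal_score` (integer 1-5), `dominant_food` and `foods` (itemized meal
#' components encoded as `"name:kcal;name:kcal"`). A missing meal score is
#' kept as `NA`, never silently coerced to a number; a score outside 1-5 is a
#' hard error since the downstream grade map is only defined on that domain.
#'
#' @param path path to a delimited text file
#' @param delim field delimiter (default `","`)
#' @return a tibble of meal events sorted by time within participant, with a
#'   `foods` list-column of per-item `name`/`kcal` tibbles
#' @export
read_meal_log <- function(path, delim = ",") {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  assert_cols(df, c("participant_id", "time", "meal", "kcal",
                    "carbs_g", "protein_g", "fat_g", "satfat_g"), "meal log")
  if (!inherits(df$time, "POSIXct")) df$time <- as.POSIXct(df$time, tz = "UTC")
  if (!"meal_score" %in% names(df)) df$meal_score <- NA_integer_
  df$meal_score <- as.integer(df$meal_score)
  bad <- !is.na(df$meal_score) & !(df$meal_score %in% 1:5)
  if (any(bad)) {
    rlang::abort(sprintf("meal_score outside {1..5} in row %d: %d",
                         which(bad)[1], df$meal_score[which(bad)[1]]))
  }
  if (any(df$kcal < 0, na.rm = TRUE)) rlang::abort("negative kcal in meal log")
  if (!"dominant_food" %in% names(df)) df$dominant_food <- NA_character_
  df$foods <- if ("foods" %in% names(df)) lapply(df$foods, parse_foods) else
    replicate(nrow(df), empty_foods(), simplify = FALSE)
  dplyr::arrange(df, .data$participant_id, .data$time)
}

empty_foods <- function() tibble::tibble(name = character(), kcal = numeric())

parse_foods <- function(x) {
  if (is.na(x) || !nzchar(x)) return(empty_foods())
  items <- strsplit(x, ";", fixed = TRUE)[[1]]
  parts <- strsplit(items, ":", fixed = TRUE)
  tibble::tibble(
    name = vapply(parts, `[`, character(1), 1L),
    kcal = as.numeric(vapply(parts, `[`, character(1), 2L))
  )
}

deparse_foods <- function(foods) {
  if (is.null(foods) || nrow(foods) == 0L) return(NA_character_)
  paste(sprintf("%s:%g", foods$name, foods$kcal), collapse = ";")
}

#' Write a meal log to CSV
#' @param meals meal-event tibble as returned by [read_meal_log()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_meal_log <- function(meals, path) {
  out <- tibble::as_tibble(meals)
  if ("foods" %in% names(out)) {
    out$foods <- vapply(out$foods, deparse_foods, character(1))
  }
  out$time <- format(out$time, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a taxa relative-abundance table
#'
#' Reads a long-format delimited table of per-sample taxon relative
#' abundances with columns `sample_id`, `taxon`, `level` (phylogenetic level,
#' e.g. phylum/genus/species), `phylum` (phylum lineage tag, used for the
#' Firmicutes/Bacteroidetes aggregation) and `abundance`. Abundances are
#' renormalized to sum to one within each (sample, level) stratum, because
#' relative abundances are compositional within a phylogenetic level; a
#' sample whose abundances sum to zero at some level cannot be renormalized
#' and is a hard error, as is any negative abundance.
#'
#' @param path path to a delimited text file
#' @param delim field delimiter (default tab)
#' @return a tibble with the same columns, abundances summing to 1 per
#'   (sample, level)
#' @export
read_taxa_table <- function(path, delim = "\t") {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  assert_cols(df, c("sample_id", "taxon", "level", "phylum", "abundance"),
              "taxa table")
  normalize_taxa(df)
}

#' Renormalize taxa abundances within each (sample, level) stratum
#' @param df long-format taxa tibble (see [read_taxa_table()])
#' @return tibble with abundances summing to 1 per (sample, level)
#' @export
normalize_taxa <- function(df) {
  if (any(df$abundance < 0)) rlang::abort("negative abundance in taxa table")
  df <- df |>
    dplyr::group_by(.data$sample_id, .data$level) |>
    dplyr::mutate(.total = sum(.data$abundance)) |>
    dplyr::ungroup()
  if (any(df$.total == 0)) {
    bad <- df[df$.total == 0, ][1, ]
    rlang::abort(sprintf("sample '%s' has all-zero abundances at level '%s'",
                         bad$sample_id, bad$level))
  }
  df$abundance <- df$abundance / df$.total
  df$.total <- NULL
  df
}

#' Write a taxa table to TSV
#' @param taxa long-format taxa tibble
#' @param path output path
#' @return `path`, invisibly
#' @export
write_taxa_table <- function(taxa, path) {
  readr::write_tsv(tibble::as_tibble(taxa), path)
  invisible(path)
}

#' Bundle the components of one trial into a single object
#'
#' A trial bundle gathers everything one intervention cohort produces: CGM
#' traces, meal logs, clinical panels at the declared timepoints, and taxa
#' tables. Construction checks referential integrity (every meal, panel and
#' taxa sample must belong to a listed participant) and that timepoint labels
#' are drawn from the declared ordered set.
#'
#' @param traces `cgm_trace` tibble covering all participants
#' @param meals meal-event tibble
#' @param clinical tibble with `participant_id`, `timepoint` and one column
#'   per clinical measure
#' @param taxa long taxa tibble with `participant_id`, `timepoint` columns in
#'   addition to the [read_taxa_table()] columns
#' @param timepoints ordered character vector of valid timepoint labels
#' @return an object of class `trial_bundle`
#' @export
trial_bundle <- function(traces, meals, clinical, taxa,
                         timepoints = c("baseline", "T0", "T3", "T6",
                                        "PPT", "MED")) {
  participants <- sort(unique(traces$participant_id))
  check_ids <- function(df, what) {
    extra <- setdiff(unique(df$participant_id), participants)
    if (length(extra) > 0L) {
      rlang::abort(sprintf("%s references unknown participant(s): %s",
                           what, paste(extra, collapse = ", ")))
    }
  }
  check_ids(meals, "meal log")
  check_ids(clinical, "clinical table")
  check_ids(taxa, "taxa table")
  for (df in list(clinical, taxa)) {
    bad <- setdiff(unique(df$timepoint), timepoints)
    if (length(bad) > 0L) {
      rlang::abort(sprintf("undeclared timepoint label(s): %s",
                           paste(bad, collapse = ", ")))
    }
  }
  structure(
    list(participants = participants, traces = traces, meals = meals,
         clinical = clinical, taxa = taxa, timepoints = timepoints),
    class = "trial_bundle"
  )
}

#' @export
print.trial_bundle <- function(x, ...) {
  cat(sprintf(
    "<trial_bundle> %d participants, %d CGM readings, %d meals, %d clinical rows, %d taxa rows\n",
    length(x$participants), nrow(x$traces), nrow(x$meals),
    nrow(x$clinical), nrow(x$taxa)
  ))
  invisible(x)
}

#' Write a trial bundle to a directory of delimited files
#' @param bundle a `trial_bundle`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cgm(bundle$traces, file.path(dir, "cgm.csv"))
  write_meal_log(bundle$meals, file.path(dir, "meals.csv"))
  readr::write_csv(bundle$clinical, file.path(dir, "clinical.csv"))
  write_taxa_table(bundle$taxa, file.path(dir, "taxa.tsv"))
  invisible(dir)
}

#' Read a trial bundle written by [write_bundle()]
#' @param dir directory containing `cgm.csv`, `meals.csv`, `clinical.csv`,
#'   `taxa.tsv`
#' @param timepoints ordered character vector of valid timepoint labels
#' @return a `trial_bundle`
#' @export
read_bundle <- function(dir, timepoints = c("baseline", "T0", "T3", "T6",
                                            "PPT", "MED")) {
  trial_bundle(
    traces = read_cgm(file.path(dir, "cgm.csv")),
    meals = read_meal_log(file.path(dir, "meals.csv")),
    clinical = readr::read_csv(file.path(dir, "clinical.csv"),
                               show_col_types = FALSE),
    taxa = read_taxa_table(file.path(dir, "taxa.tsv")),
    timepoints = timepoints
  )
}
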