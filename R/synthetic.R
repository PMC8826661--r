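# Synthetic trial cohorts with known ground truth.
#
# The generator emulates the data a crossover + 6-month PPT-diet trial
# produces: 15-minute CGM traces with meal-locked excursions, logged meals
# with macronutrients and predictor meal scores, clinical panels with
# injected pre-post effects, and compositional taxa tables with injected
# change-outcome correlations. Default parameter scales are pinned to the
# cohort summaries the trial printed (n = 23 split 11/12 by sequence,
# HbA1c 6.8 +/- 0.4%, FPG 149.7 +/- 19 mg/dl, ~96 readings/day, a -20
# mg/dl x h diet effect on average PPGR with within-person difference SD 16,
# 6-month effects such as HbA1c -0.39 +/- 0.48%).
#
# Meal excursions are raised-cosine bumps spanning exactly the 2-h PPGR
# window: a bump of peak A mg/dl has closed-form incremental area A x 1 h,
# so the generative PPGR of every meal is known exactly and the CGM metrics
# are falsifiable by round trip.

#' Synthetic cohort configuration
#'
#' All simulation knobs in one object. Defaults reproduce the study
#' conditions of the emulated trial at the printed parameter scales; see the
#' package vignette for the provenance of each default.
#'
#' @param n_participants cohort size (default 23)
#' @param n_sequence_ppt_first participants allocated to the PPT-MED
#'   sequence (default 11; the rest start with MED)
#' @param sampling_minutes CGM sampling interval (default 15; must divide
#'   24 h)
#' @param period_days length of each crossover diet period in days
#'   (default 14)
#' @param glucose_mean,glucose_sd population mean/SD of the person-level
#'   mean glucose, mg/dl (defaults 150, 19)
#' @param ar_phi,ar_sd AR(1) autocorrelation and innovation SD of the
#'   baseline glucose wander, mg/dl (defaults 0.3, 0.5: deliberately small,
#'   about 0.5 mg/dl stationary SD, so each meal's generative PPGR imprints
#'   recoverably on the trace and metric defects are detectable rather than
#'   drowned in simulated noise; person-level variability enters through
#'   the response model, not sensor noise)
#' @param ppgr_base cohort mean generative meal PPGR under the reference
#'   (MED) arm, mg/dl x h (default 55)
#' @param carb_slope generative PPGR slope on the meal's centred
#'   carbohydrate grams, mg/dl x h per g (default 1; the slope drives
#'   within-arm meal-to-meal variation, while `diet_effect_ppgr` carries the
#'   whole between-arm contrast)
#' @param person_sd SD of the person random effect on PPGR (default 12)
#' @param person_food_sd SD tau of the person x food interaction on PPGR
#'   (default 10)
#' @param residual_sd residual PPGR SD sigma per meal (default 8)
#' @param diet_effect_ppgr injected PPT-minus-MED effect on average PPGR,
#'   mg/dl x h (default -20)
#' @param crossover_diff_sd SD of the within-person between-diet difference
#'   in average PPGR (default 16)
#' @param kcal_target daily energy target, kcal (default 2000)
#' @param clinical_t0 named list of `c(mean, sd)` for each panel measure at
#'   T0
#' @param clinical_effects named list of `c(mean, sd)` 6-month changes
#'   (T6 - T0) injected per measure
#' @param taxa_levels named list: per phylogenetic level, a named numeric
#'   vector of Dirichlet concentration parameters (names are taxa;
#'   `phylum|taxon` syntax carries the lineage tag)
#' @param injected_assoc list of associations to inject, each a list with
#'   `taxon`, `level`, `outcome`, `r`, `delta_sd`
#' @return a list of class `cohort_config`
#' @export
cohort_config <- function(n_participants = 23,
                          n_sequence_ppt_first = 11,
                          sampling_minutes = 15,
                          period_days = 14,
                          glucose_mean = 150, glucose_sd = 19,
                          ar_phi = 0.3, ar_sd = 0.5,
                          ppgr_base = 55,
                          carb_slope = 1, person_sd = 12,
                          person_food_sd = 10, residual_sd = 8,
                          diet_effect_ppgr = -20, crossover_diff_sd = 16,
                          kcal_target = 2000,
                          clinical_t0 = list(
                            hba1c = c(6.8, 0.4),
                            fpg = c(149.7, 19),
                            fructosamine = c(295.1, 35.5),
                            insulin = c(12, 5),
                            triglycerides = c(153.5, 76.4),
                            total_cholesterol = c(200.7, 40),
                            ldl = c(125.6, 28),
                            hdl = c(47.4, 9),
                            weight = c(87.5, 21.5),
                            body_fat = c(33.7, 10.9),
                            waist = c(102, 14.8)
                          ),
                          clinical_effects = list(
                            hba1c = c(-0.39, 0.48),
                            fpg = c(-16.4, 24.2),
                            fructosamine = c(-26.7, 22.5),
                            insulin = c(-2.3, 4.0),
                            triglycerides = c(-49, 46),
                            total_cholesterol = c(0, 20),
                            ldl = c(-4.7, 20),
                            hdl = c(0, 6),
                            weight = c(-3, 3.5),
                            body_fat = c(-2.5, 3),
                            waist = c(-4.7, 3.7)
                          ),
                          taxa_levels = default_taxa_levels(),
                          injected_assoc = list(
                            list(taxon = "Faecalibacterium", level = "genus",
                                 outcome = "fpg", r = 0.6, delta_sd = 0.01),
                            list(taxon = "Bacteroides", level = "genus",
                                 outcome = "hba1c", r = -0.65, delta_sd = 0.01)
                          )) {
  stopifnot(
    n_participants >= 2, n_sequence_ppt_first <= n_participants,
    (24 * 60) %% sampling_minutes == 0,
    ar_sd >= 0, person_sd >= 0, person_food_sd >= 0, residual_sd >= 0,
    crossover_diff_sd >= 0
  )
  structure(as.list(environment()), class = "cohort_config")
}

#' Default taxa model: Dirichlet concentrations by phylogenetic level
#'
#' Taxon names use `phylum|taxon` syntax so generated tables carry the
#' lineage tag needed for the Firmicutes/Bacteroidetes aggregation.
#' Concentrations are scaled so genus-level compositions show realistic
#' dominance of a few genera.
#'
#' @return named list of named numeric vectors
#' @export
default_taxa_levels <- function() {
  list(
    phylum = c("Firmicutes|Firmicutes" = 12, "Bacteroidetes|Bacteroidetes" = 8,
               "Actinobacteria|Actinobacteria" = 2,
               "Proteobacteria|Proteobacteria" = 1.5,
               "Verrucomicrobia|Verrucomicrobia" = 0.5),
    genus = c("Firmicutes|Blautia" = 4, "Firmicutes|Faecalibacterium" = 5,
              "Firmicutes|Roseburia" = 2, "Firmicutes|Eubacterium" = 2,
              "Firmicutes|Veillonella" = 0.8, "Firmicutes|Dialister" = 0.8,
              "Bacteroidetes|Bacteroides" = 6, "Bacteroidetes|Prevotella" = 2,
              "Bacteroidetes|Alistipes" = 1.5,
              "Actinobacteria|Bifidobacterium" = 1.2,
              "Proteobacteria|Escherichia" = 0.7,
              "Verrucomicrobia|Akkermansia" = 0.5)
  )
}

# One Dirichlet draw via normalized gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate one CGM trace with meal-locked excursions
#'
#' Baseline glucose is an AR(1) process around the person's mean sampled on
#' the regular CGM grid; each meal adds a raised-cosine excursion spanning
#' the 2-h post-meal window whose peak equals the meal's generative PPGR in
#' mg/dl x h (the bump's incremental area is exactly peak x 1 h).
#' Bit-reproducible given `seed`.
#'
#' @param participant_id participant label
#' @param start POSIXct start of the trace
#' @param days trace length in days
#' @param person_mean person's mean glucose, mg/dl
#' @param meal_schedule tibble with `time` (POSIXct) and `gen_iauc`
#'   (generative PPGR, mg/dl x h); may be empty
#' @param config a [cohort_config()]
#' @param seed integer seed
#' @return a `cgm_trace` tibble
#' @export
generate_trace <- function(participant_id, start, days, person_mean,
                           meal_schedule = NULL, config = cohort_config(),
                           seed = 1) {
  set.seed(seed)
  step_s <- config$sampling_minutes * 60
  times <- start + seq(0, days * 86400 - step_s, by = step_s)
  n <- length(times)
  if (config$ar_sd > 0) {
    eps <- stats::rnorm(n, 0, config$ar_sd)
    noise <- as.numeric(stats::filter(eps, config$ar_phi, method = "recursive"))
  } else {
    noise <- rep(0, n)
  }
  glucose <- person_mean + noise
  if (!is.null(meal_schedule) && nrow(meal_schedule) > 0L) {
    tt <- as.numeric(times)
    for (i in seq_len(nrow(meal_schedule))) {
      t0 <- as.numeric(meal_schedule$time[i])
      s <- (tt - t0) / 7200 # fraction of the 2-h window
      in_win <- s >= 0 & s <= 1
      glucose[in_win] <- glucose[in_win] +
        meal_schedule$gen_iauc[i] * sin(pi * s[in_win])^2
    }
  }
  glucose <- pmin(pmax(glucose, GLUCOSE_RANGE[1]), GLUCOSE_RANGE[2])
  as_cgm_trace(tibble::tibble(participant_id = participant_id, time = times,
                              glucose = glucose))
}

# Fixed daily meal slots (hours of day, grid-aligned at 15 min)
meal_slots <- function() {
  tibble::tibble(
    slot = c("breakfast", "lunch", "dinner", "snack"),
    hour = c(8, 13, 19, 16.5),
    kcal_share = c(0.25, 0.35, 0.3, 0.1)
  )
}

#' Simulate a meal log for one diet period
#'
#' Logs breakfast, lunch, dinner and one snack per day at fixed grid-aligned
#' times between 07:00 and 22:00. Meal energy follows the configured daily
#' target split across slots with lognormal day-to-day variation; macronutrient
#' shares differ by diet (the MED arm is carbohydrate-rich, the PPT arm
#' carbohydrate-poor and fat-rich, mirroring the consumed compositions of
#' the two arms). Meal scores are drawn low (1-2) for PPT meals and across
#' the full range for MED meals. Bit-reproducible given `seed`.
#'
#' @param participant_id participant label
#' @param start POSIXct first day of the period
#' @param days period length in days
#' @param diet `"PPT"` or `"MED"`
#' @param config a [cohort_config()]
#' @param seed integer seed
#' @return meal-event tibble (columns as in [read_meal_log()], plus `slot`)
#' @export
generate_meal_log <- function(participant_id, start, days,
                              diet = c("PPT", "MED"),
                              config = cohort_config(), seed = 1) {
  diet <- match.arg(diet)
  set.seed(seed)
  slots <- meal_slots()
  macro_share <- if (diet == "MED") {
    c(carb = 0.46, protein = 0.18, fat = 0.29) # % of energy
  } else {
    c(carb = 0.22, protein = 0.22, fat = 0.51)
  }
  rows <- list()
  day0 <- as.POSIXct(format(start, "%Y-%m-%d"), tz = "UTC")
  for (d in seq_len(days) - 1L) {
    day_kcal <- config$kcal_target * exp(stats::rnorm(1, 0, 0.1))
    for (j in seq_len(nrow(slots))) {
      kcal <- day_kcal * slots$kcal_share[j] * exp(stats::rnorm(1, 0, 0.15))
      score <- if (diet == "PPT") sample(1:2, 1, prob = c(0.7, 0.3)) else
        sample(1:5, 1, prob = c(0.1, 0.2, 0.3, 0.25, 0.15))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant_id = participant_id,
        time = day0 + d * 86400 + slots$hour[j] * 3600,
        meal = sprintf("%s_%s_d%02d", tolower(diet), slots$slot[j], d + 1L),
        slot = slots$slot[j],
        kcal = kcal,
        carbs_g = kcal * macro_share[["carb"]] / 4,
        protein_g = kcal * macro_share[["protein"]] / 4,
        fat_g = kcal * macro_share[["fat"]] / 9,
        satfat_g = kcal * macro_share[["fat"]] * 0.3 / 9,
        meal_score = as.integer(score),
        dominant_food = NA_character_
      )
    }
  }
  meals <- dplyr::arrange(dplyr::bind_rows(rows), .data$time)
  meals$foods <- replicate(nrow(meals), empty_foods(), simplify = FALSE)
  meals
}

#' Simulate clinical panels and taxa tables with injected effects
#'
#' T0 panels draw each measure from its configured population mean/SD;
#' T3 panels add half the configured 6-month effect plus noise; T6 panels
#' add the full effect plus noise. Taxa compositions are Dirichlet draws per
#' phylogenetic level at baseline; T6 compositions perturb the baseline with
#' noise and, for each configured injected association, construct the target
#' taxon's change to correlate with the matching clinical change at the
#' requested Pearson r (before the compositional renormalization, which
#' attenuates it slightly). Bit-reproducible given `seed`.
#'
#' @param config a [cohort_config()]
#' @param seed integer seed
#' @return list with `clinical` (tibble: `participant_id`, `timepoint`, one
#'   column per measure), `taxa` (long tibble with `participant_id`,
#'   `timepoint`, `sample_id`, `taxon`, `level`, `phylum`, `abundance`), and
#'   `truth` (the injected effect and association parameters)
#' @export
generate_clinical_and_taxa <- function(config = cohort_config(), seed = 1) {
  set.seed(seed)
  n <- config$n_participants
  ids <- sprintf("P%02d", seq_len(n))

  t0 <- tibble::tibble(participant_id = ids, timepoint = "T0")
  for (m in names(config$clinical_t0)) {
    ms <- config$clinical_t0[[m]]
    t0[[m]] <- stats::rnorm(n, ms[1], ms[2])
  }
  t0$hba1c <- pmin(pmax(t0$hba1c, 5), 12)
  make_later <- function(label, frac) {
    tp <- t0
    tp$timepoint <- label
    for (m in names(config$clinical_effects)) {
      ef <- config$clinical_effects[[m]]
      tp[[m]] <- t0[[m]] + frac * ef[1] + stats::rnorm(n, 0, ef[2] * sqrt(frac))
    }
    tp
  }
  t3 <- make_later("T3", 0.5)
  t6 <- make_later("T6", 1)
  clinical <- dplyr::bind_rows(t0, t3, t6)

  # taxa: baseline Dirichlet, T6 = baseline + noise (+ injected signal)
  changes <- stats::setNames(
    lapply(names(config$clinical_effects), function(m) t6[[m]] - t0[[m]]),
    names(config$clinical_effects)
  )
  taxa_rows <- list()
  for (lev in names(config$taxa_levels)) {
    alpha <- config$taxa_levels[[lev]]
    tags <- strsplit(names(alpha), "|", fixed = TRUE)
    phyla <- vapply(tags, `[`, character(1), 1L)
    taxa_names <- vapply(tags, `[`, character(1), 2L)
    base <- t(vapply(seq_len(n), function(i) rdirichlet1(alpha),
                     numeric(length(alpha))))
    delta <- matrix(stats::rnorm(n * length(alpha), 0, 0.005),
                    nrow = n)
    for (assoc in config$injected_assoc) {
      if (assoc$level != lev) next
      k <- which(taxa_names == assoc$taxon)
      if (length(k) != 1L) next
      d_out <- changes[[assoc$outcome]]
      z_out <- (d_out - mean(d_out)) / stats::sd(d_out)
      eps <- stats::rnorm(n)
      eps <- (eps - mean(eps)) / stats::sd(eps)
      # remove the component of eps along z_out so the pre-clip r is exact
      eps <- eps - sum(eps * z_out) / sum(z_out * z_out) * z_out
      eps <- eps / stats::sd(eps)
      z <- assoc$r * z_out + sqrt(1 - assoc$r^2) * eps
      delta[, k] <- assoc$delta_sd * z
    }
    end <- pmax(base + delta, 1e-6)
    end <- end / rowSums(end)
    for (tp in c("baseline", "T6")) {
      ab <- if (tp == "baseline") base else end
      taxa_rows[[paste(lev, tp)]] <- tibble::tibble(
        participant_id = rep(ids, each = length(alpha)),
        timepoint = tp,
        sample_id = paste0(rep(ids, each = length(alpha)), "_", tp),
        taxon = rep(taxa_names, n),
        level = lev,
        phylum = rep(phyla, n),
        abundance = as.numeric(t(ab))
      )
    }
  }
  list(clinical = clinical,
       taxa = dplyr::bind_rows(taxa_rows),
       truth = list(clinical_effects = config$clinical_effects,
                    injected_assoc = config$injected_assoc))
}

#' Simulate per-participant crossover outcome summaries
#'
#' The summary-level view of the crossover: each participant's average PPGR
#' under MED draws around the cohort mean with between-person spread, and
#' the PPT value adds the injected diet effect plus within-person noise
#' (`crossover_diff_sd` is the SD of the within-person PPT-minus-MED
#' difference). This is the generator used for effect-recovery and type-I
#' calibration studies, where thousands of replicates of the full CGM
#' pipeline would add nothing but runtime.
#'
#' @param config a [cohort_config()]
#' @param seed integer seed
#' @param effect diet effect override (defaults to the configured
#'   `diet_effect_ppgr`; set 0 for a null simulation)
#' @return crossover records tibble (`participant_id`, `sequence`,
#'   `period`, `diet`, `value`)
#' @export
simulate_crossover <- function(config = cohort_config(), seed = 1,
                               effect = config$diet_effect_ppgr) {
  set.seed(seed)
  n <- config$n_participants
  ids <- sprintf("P%02d", seq_len(n))
  seqs <- rep(c("PPT-MED", "MED-PPT"),
              c(config$n_sequence_ppt_first, n - config$n_sequence_ppt_first))
  med <- stats::rnorm(n, config$ppgr_base, config$person_sd) # average PPGR under MED
  ppt <- med + effect + stats::rnorm(n, 0, config$crossover_diff_sd)
  ppt <- pmax(ppt, 0)
  med <- pmax(med, 0)
  tibble::tibble(
    participant_id = rep(ids, 2),
    sequence = rep(seqs, 2),
    diet = rep(c("PPT", "MED"), each = n),
    period = ifelse(rep(seqs, 2) == "PPT-MED",
                    ifelse(rep(c("PPT", "MED"), each = n) == "PPT", 1L, 2L),
                    ifelse(rep(c("PPT", "MED"), each = n) == "PPT", 2L, 1L)),
    value = c(ppt, med)
  )
}

#' Simulate a meal-level feature dataset with known signal structure
#'
#' Generates meals with macronutrients, person-level clinical features and
#' taxa-abundance features, and a generative iAUC combining a carbohydrate
#' slope, a person random effect, a person x microbiome interaction (the
#' person's carbohydrate sensitivity depends on their abundance of the
#' first taxon feature), and residual noise. `interaction_sd` = 0 reduces
#' to a purely carbohydrate-driven response; `carb_slope` = 0 with
#' `interaction_sd` = 0 is pure noise.
#'
#' @param n_persons number of persons
#' @param meals_per_person meals per person
#' @param carb_slope common carbohydrate slope, mg/dl x h per g
#' @param person_sd SD of the additive person effect
#' @param interaction_sd scale of the person x taxa carbohydrate-sensitivity
#'   interaction
#' @param noise_sd residual SD
#' @param seed integer seed
#' @return tibble with `participant_id`, meal features, person features,
#'   `taxon_1`..`taxon_3` and `iauc`
#' @export
simulate_meal_features <- function(n_persons = 20, meals_per_person = 15,
                                   carb_slope = 0.8, person_sd = 8,
                                   interaction_sd = 0, noise_sd = 8,
                                   seed = 1) {
  set.seed(seed)
  ids <- sprintf("P%02d", seq_len(n_persons))
  person <- tibble::tibble(
    participant_id = ids,
    hba1c = stats::rnorm(n_persons, 6.8, 0.4),
    fpg = stats::rnorm(n_persons, 150, 19),
    weight = stats::rnorm(n_persons, 87, 20),
    taxon_1 = stats::runif(n_persons),
    taxon_2 = stats::runif(n_persons),
    taxon_3 = stats::runif(n_persons),
    person_effect = stats::rnorm(n_persons, 0, person_sd)
  )
  meals <- tidyr::expand_grid(participant_id = ids,
                              meal_idx = seq_len(meals_per_person))
  meals <- dplyr::inner_join(meals, person, by = "participant_id")
  meals$carbs_g <- stats::runif(nrow(meals), 10, 90)
  meals$fat_g <- stats::runif(nrow(meals), 5, 50)
  meals$protein_g <- stats::runif(nrow(meals), 5, 40)
  sensitivity <- carb_slope + interaction_sd * (meals$taxon_1 - 0.5) * 2
  meals$iauc <- pmax(
    20 + sensitivity * meals$carbs_g + meals$person_effect +
      stats::rnorm(nrow(meals), 0, noise_sd),
    0
  )
  meals$person_effect <- NULL
  meals$meal_idx <- NULL
  meals
}

#' Generate a complete synthetic trial bundle
#'
#' Ties the generators together into one desk-scale bundle: for each
#' participant, two crossover periods (sequence-ordered PPT and MED) of CGM
#' trace plus meal log, with every meal's generative PPGR drawn from the
#' configured response model (carbohydrate slope, person effect, diet
#' effect, residual) and imprinted on the trace; clinical panels at
#' T0/T3/T6; and taxa tables at baseline/T6. The returned `truth` element
#' records every generative quantity needed to audit downstream estimates,
#' including each logged meal's generative iAUC.
#'
#' @param config a [cohort_config()]
#' @param seed integer seed
#' @param period_days override of the configured crossover period length
#'   (shorten for fast tests)
#' @return list with `bundle` (a [trial_bundle()]), `records` (per-period
#'   average generative PPGR, crossover records layout) and `truth`
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1,
                            period_days = config$period_days) {
  set.seed(seed)
  n <- config$n_participants
  ids <- sprintf("P%02d", seq_len(n))
  seqs <- rep(c("PPT-MED", "MED-PPT"),
              c(config$n_sequence_ppt_first, n - config$n_sequence_ppt_first))
  person_mean <- stats::rnorm(n, config$glucose_mean, config$glucose_sd)
  person_effect <- stats::rnorm(n, 0, config$person_sd)
  sub_seeds <- sample.int(2^31 - 2, n * 4)

  traces <- list(); meal_logs <- list(); record_rows <- list()
  start0 <- as.POSIXct("2021-03-01 00:00:00", tz = "UTC")
  for (i in seq_len(n)) {
    diets <- if (seqs[i] == "PPT-MED") c("PPT", "MED") else c("MED", "PPT")
    for (per in 1:2) {
      diet <- diets[per]
      start <- start0 + (per - 1L) * period_days * 86400
      meals <- generate_meal_log(ids[i], start, period_days, diet = diet,
                                 config = config,
                                 seed = sub_seeds[(i - 1) * 4 + per])
      set.seed(sub_seeds[(i - 1) * 4 + 2 + per])
      diet_shift <- if (diet == "PPT") config$diet_effect_ppgr else 0
      food_effect <- stats::rnorm(nrow(meals), 0, config$person_food_sd)
      # carbohydrate drives within-arm variation (centred per period);
      # the between-arm contrast is carried by diet_effect_ppgr alone
      carbs_c <- meals$carbs_g - mean(meals$carbs_g)
      gen_iauc <- pmax(
        config$ppgr_base + config$carb_slope * carbs_c + person_effect[i] +
          diet_shift + food_effect +
          stats::rnorm(nrow(meals), 0, config$residual_sd),
        2
      )
      meals$gen_iauc <- gen_iauc
      tr <- generate_trace(ids[i], start, period_days, person_mean[i],
                           meal_schedule = meals[, c("time", "gen_iauc")],
                           config = config,
                           seed = sub_seeds[(i - 1) * 4 + per] + 1L)
      traces[[length(traces) + 1L]] <- tr
      meal_logs[[length(meal_logs) + 1L]] <- meals
      record_rows[[length(record_rows) + 1L]] <- tibble::tibble(
        participant_id = ids[i], sequence = seqs[i], period = per,
        diet = diet, value = mean(gen_iauc)
      )
    }
  }
  ct <- generate_clinical_and_taxa(config, seed = seed + 1L)
  meals_all <- dplyr::bind_rows(meal_logs)
  bundle <- trial_bundle(
    traces = as_cgm_trace(dplyr::bind_rows(traces)),
    meals = meals_all[, setdiff(names(meals_all), "gen_iauc")],
    clinical = ct$clinical,
    taxa = ct$taxa
  )
  list(bundle = bundle,
       records = dplyr::bind_rows(record_rows),
       truth = c(ct$truth,
                 list(diet_effect_ppgr = config$diet_effect_ppgr,
                      person_mean = stats::setNames(person_mean, ids),
                      meal_gen_iauc = meals_all[, c("participant_id", "time",
                                                    "meal", "gen_iauc")])))
}
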