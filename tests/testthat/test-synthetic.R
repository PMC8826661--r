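test_that("trace generation is bit-reproducible and respects zero-noise configs", {
  cfg <- cohort_config(ar_sd = 0)
  t0 <- as.POSIXct("2021-03-01", tz = "UTC")

  flat <- generate_trace("P1", t0, 1, 150, meal_schedule = NULL,
                         config = cfg, seed = 4)
  expect_true(all(flat$glucose == 150))
  expect_equal(nrow(flat), 96L)

  noisy_cfg <- cohort_config()
  a <- generate_trace("P1", t0, 2, 150, config = noisy_cfg, seed = 9)
  b <- generate_trace("P1", t0, 2, 150, config = noisy_cfg, seed = 9)
  expect_identical(a, b)
  expect_false(all(a$glucose == 150))
})

test_that("meal excursions round-trip through the PPGR metric", {
  t0 <- as.POSIXct("2021-03-01", tz = "UTC")
  sched <- tibble::tibble(time = t0 + 8 * 3600, gen_iauc = 60)

  # noise-free: the raised-cosine bump integrates exactly on the 15-min grid
  exact <- generate_trace("P1", t0, 1, 150, sched,
                          config = cohort_config(ar_sd = 0), seed = 1)
  expect_equal(meal_ppgr(exact, sched$time)$iauc, 60, tolerance = 1e-10)

  # with the default AR(1) sensor noise the measured PPGR stays within 5%
  noisy <- generate_trace("P1", t0, 1, 150, sched,
                          config = cohort_config(), seed = 2)
  expect_lt(abs(meal_ppgr(noisy, sched$time)$iauc - 60) / 60, 0.05)
})

test_that("meal logs are seeded, slot-structured and near the energy target", {
  t0 <- as.POSIXct("2021-03-01", tz = "UTC")
  cfg <- cohort_config(kcal_target = 2000)
  log1 <- generate_meal_log("P1", t0, 14, diet = "PPT", config = cfg, seed = 5)
  log2 <- generate_meal_log("P1", t0, 14, diet = "PPT", config = cfg, seed = 5)
  expect_identical(log1, log2)

  expect_equal(nrow(log1), 14L * 4L)
  hours <- as.numeric(format(log1$time, "%H"))
  expect_true(all(hours >= 7 & hours <= 22))
  daily <- tapply(log1$kcal, as.Date(log1$time), sum)
  expect_lt(abs(mean(daily) - 2000) / 2000, 0.10)

  # PPT meals carry low scores, MED spans the range
  expect_true(all(log1$meal_score <= 2))
  med <- generate_meal_log("P1", t0, 14, diet = "MED", config = cfg, seed = 5)
  expect_gt(max(med$meal_score), 2)
})

test_that("clinical panels apply configured effects and taxa compose to one", {
  zero_cfg <- cohort_config(
    n_participants = 6, n_sequence_ppt_first = 3,
    clinical_effects = lapply(cohort_config()$clinical_effects,
                              function(x) c(0, 0))
  )
  ct0 <- generate_clinical_and_taxa(zero_cfg, seed = 20)
  t0 <- ct0$clinical[ct0$clinical$timepoint == "T0", ]
  t6 <- ct0$clinical[ct0$clinical$timepoint == "T6", ]
  expect_equal(t6$hba1c, t0$hba1c)
  expect_equal(t6$fpg, t0$fpg)

  ct <- generate_clinical_and_taxa(cohort_config(n_participants = 8,
                                                 n_sequence_ppt_first = 4),
                                   seed = 21)
  sums <- ct$taxa |>
    dplyr::group_by(sample_id, level) |>
    dplyr::summarise(s = sum(abundance), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("injected taxa-outcome correlations are recovered", {
  cfg <- cohort_config(
    n_participants = 100, n_sequence_ppt_first = 50,
    injected_assoc = list(list(taxon = "Faecalibacterium", level = "genus",
                               outcome = "fpg", r = 0.9, delta_sd = 0.01))
  )
  ct <- generate_clinical_and_taxa(cfg, seed = 30)
  ch <- taxa_changes(ct$taxa)
  wide <- ct$clinical |>
    dplyr::select(participant_id, timepoint, fpg) |>
    tidyr::pivot_wider(names_from = timepoint, values_from = fpg)
  d_fpg <- wide$T6 - wide$T0
  d_taxon <- ch$delta[ch$taxon == "Faecalibacterium" & ch$level == "genus"]
  r <- cor(d_taxon, d_fpg)
  expect_gt(r, 0.8)
  expect_lt(r, 0.97)
})

test_that("crossover outcome simulation carries the injected diet effect", {
  rec <- simulate_crossover(cohort_config(), seed = 2)
  expect_equal(nrow(rec), 46L)
  expect_setequal(unique(rec$diet), c("PPT", "MED"))
  # each participant holds one period per diet, opposite periods
  per <- tapply(rec$period, rec$participant_id, function(x) sort(x))
  expect_true(all(vapply(per, identical, logical(1), c(1L, 2L))))

  null_rec <- simulate_crossover(cohort_config(), seed = 2, effect = 0)
  expect_identical(dim(null_rec), dim(rec))
})

test_that("a generated cohort recovers the injected diet effect end to end", {
  cfg <- cohort_config(n_participants = 8, n_sequence_ppt_first = 4,
                       residual_sd = 4, person_food_sd = 4)
  sim <- generate_cohort(cfg, seed = 42, period_days = 3)

  # per-meal PPGRs measured from the CGM traces, averaged per diet period
  pp <- suppressMessages(ppgr_table(sim$bundle$traces, sim$bundle$meals))
  expect_gt(mean(pp$computable), 0.95)
  measured <- pp |>
    dplyr::filter(computable) |>
    dplyr::mutate(diet = ifelse(grepl("^ppt", meal), "PPT", "MED")) |>
    dplyr::group_by(participant_id, diet) |>
    dplyr::summarise(value = mean(iauc), .groups = "drop")
  res <- crossover_effect(
    dplyr::inner_join(measured,
                      dplyr::distinct(sim$records[, c("participant_id",
                                                      "sequence", "diet",
                                                      "period")]),
                      by = c("participant_id", "diet")),
    "paired_t")
  # injected -20 effect, small cohort: the estimate must land near it
  expect_lt(res$estimate, -10)
  expect_gt(res$estimate, -30)

  # and the generative per-period means recover it tightly
  res_truth <- crossover_effect(sim$records, "paired_t")
  half <- qt(0.975, res_truth$n - 1) * res_truth$dispersion / sqrt(res_truth$n)
  expect_lt(abs(res_truth$estimate - (-20)), half + 5)
})

test_that("cohort generation is reproducible given (config, seed)", {
  cfg <- cohort_config(n_participants = 3, n_sequence_ppt_first = 2)
  s1 <- generate_cohort(cfg, seed = 8, period_days = 1)
  s2 <- generate_cohort(cfg, seed = 8, period_days = 1)
  expect_identical(s1$bundle$traces$glucose, s2$bundle$traces$glucose)
  expect_identical(s1$bundle$meals$kcal, s2$bundle$meals$kcal)
  expect_identical(s1$bundle$taxa$abundance, s2$bundle$taxa$abundance)
  s3 <- generate_cohort(cfg, seed = 9, period_days = 1)
  expect_false(identical(s1$bundle$traces$glucose, s3$bundle$traces$glucose))
})
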