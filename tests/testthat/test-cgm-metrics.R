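test_that("meal_ppgr handles flat, peaked and below-baseline excursions", {
  # constant trace: no excursion, zero incremental area
  flat <- make_trace(seq(0, 2, by = 0.25), rep(100, 9))
  expect_equal(meal_ppgr(flat, t_origin)$iauc, 0)

  # rise from 100 to 160 at 60 min, back to 100 at 120 min: area of a
  # triangle of height 60 over 2 h = 60 mg/dl x h
  hours <- seq(0, 2, by = 0.25)
  g <- approx(c(0, 1, 2), c(100, 160, 100), xout = hours)$y
  peak <- make_trace(hours, g)
  res <- meal_ppgr(peak, t_origin)
  expect_equal(res$iauc, 60)
  expect_equal(res$baseline, 100)
  expect_equal(oracle_iauc(peak, 0, 2), 60, tolerance = 1e-9)

  # dip below baseline and back: clipped to zero
  dip <- make_trace(hours, approx(c(0, 1, 2), c(100, 80, 100), xout = hours)$y)
  expect_equal(meal_ppgr(dip, t_origin)$iauc, 0)
  # net-AUC flag integrates the signed area instead
  expect_equal(meal_ppgr(dip, t_origin, clip_below_baseline = FALSE)$iauc, -20)
})

test_that("meal_ppgr is invariant to readings outside the window and flags poor coverage", {
  hours <- seq(0, 2, by = 0.25)
  g <- approx(c(0, 1, 2), c(100, 160, 100), xout = hours)$y
  base <- make_trace(hours, g)
  padded <- make_trace(c(-3, -2, hours, 3, 4), c(90, 95, g, 150, 80))
  expect_equal(meal_ppgr(padded, t_origin)$iauc, meal_ppgr(base, t_origin)$iauc)

  # only the first half-hour of the window covered -> uncomputable
  short <- make_trace(seq(0, 0.5, by = 0.25), c(100, 120, 130))
  res <- meal_ppgr(short, t_origin)
  expect_false(res$computable)
  expect_true(is.na(res$iauc))
})

test_that("averaged_ppgr blocks readings within connections", {
  # constant trace: every block has zero incremental area
  expect_equal(averaged_ppgr(day_trace(rep(120, 96))), 0)

  # 18 readings: one flat block and one symmetric +40 bump block
  hours <- seq(0, 4.25, by = 0.25)
  bump <- 40 * sin(pi * pmax(pmin((hours - 2.25) / 2, 1), 0))^2
  tr <- make_trace(hours, 100 + bump)
  got <- averaged_ppgr(tr)
  expect_equal(got, oracle_averaged_ppgr(tr), tolerance = 1e-9)
  expect_gt(got, 0)

  # fewer readings than one block: absent value
  expect_true(is.na(averaged_ppgr(make_trace(seq(0, 1.75, by = 0.25),
                                             rep(100, 8)))))

  # blocks never straddle connections: processing connections separately
  # gives the same answer
  two_conn <- make_trace(c(seq(0, 2, by = 0.25), seq(10, 12, by = 0.25)),
                         c(100 + 30 * sin(pi * seq(0, 1, length.out = 9))^2,
                           110 + 20 * sin(pi * seq(0, 1, length.out = 9))^2))
  expect_equal(unique(two_conn$connection), c(1L, 2L))
  separate <- vapply(split(two_conn, two_conn$connection),
                     function(x) averaged_ppgr(as_cgm_trace(x)), numeric(1))
  expect_equal(averaged_ppgr(two_conn), mean(separate))
})

test_that("glucose_cv is sd/mean, scale invariant, and absent for short traces", {
  expect_equal(glucose_cv(day_trace(rep(140, 96))), 0)

  alternating <- day_trace(c(90, 110))
  x <- rep(c(90, 110), 48)
  expect_equal(glucose_cv(alternating), sd(x) / mean(x))
  expect_equal(sd(x) / mean(x), 0.1005, tolerance = 1e-3)

  scaled <- day_trace(c(90, 110) * 2.5)
  expect_equal(glucose_cv(scaled), glucose_cv(alternating))

  expect_true(is.na(glucose_cv(make_trace(0, 100))))
})

test_that("time_above uses the strictly-above convention with interpolated crossings", {
  expect_equal(time_above(day_trace(rep(150, 96))),
               c("140" = 24, "150" = 0, "160" = 0, "170" = 0, "180" = 0))
  expect_equal(unname(time_above(day_trace(rep(130, 96)))), rep(0, 5))

  # 12 h at 160 then 12 h at 120, one linear 15-min transition
  hours <- seq(0, 24 - 0.25, by = 0.25)
  g <- ifelse(hours < 12, 160, 120)
  tr <- make_trace(hours, g)
  got <- time_above(tr)
  expect_equal(got, oracle_time_above(tr), tolerance = 1e-9)
  # crossing of 140 happens halfway through the transition segment
  expect_equal(unname(got["140"]), 24 * (11.75 + 0.125) / 23.75, tolerance = 1e-9)
})

test_that("time_above is monotonically non-increasing in the threshold", {
  for (seed in 1:5) {
    ta <- time_above(random_day_trace(seed), thresholds = seq(100, 200, by = 10),
                     min_daily_readings = 48)
    expect_true(all(diff(ta) <= 1e-12))
    expect_true(all(ta >= 0 & ta <= 24))
  }
})

test_that("hourly_ppgr_profile buckets by meal hour", {
  pp <- tibble::tibble(
    time = t_origin + c(8, 8, 12, 12) * 3600,
    iauc = c(50, 50, 30, 50),
    computable = TRUE
  )
  prof <- hourly_ppgr_profile(pp)
  expect_equal(prof$hour, c(8L, 12L))
  expect_equal(prof$mean_ppgr, c(50, 40))

  # grouped means equal stratified recomputation on a random log
  set.seed(42)
  pp2 <- tibble::tibble(
    time = t_origin + sample(7:21, 60, replace = TRUE) * 3600 +
      sample(0:59, 60, replace = TRUE) * 60,
    iauc = runif(60, 0, 90),
    computable = runif(60) > 0.1
  )
  prof2 <- hourly_ppgr_profile(pp2)
  manual <- tapply(pp2$iauc[pp2$computable],
                   as.integer(format(pp2$time[pp2$computable], "%H", tz = "UTC")),
                   mean)
  expect_equal(prof2$mean_ppgr, as.numeric(manual[as.character(prof2$hour)]))
})

test_that("ppgr_percentiles match the linear-interpolation definition", {
  single <- ppgr_percentiles(42)
  expect_equal(unname(single), rep(42, 5))

  grid <- ppgr_percentiles(0:100)
  expect_equal(unname(grid["50"]), 50)

  set.seed(9)
  v <- rexp(37, 1 / 40)
  expect_equal(ppgr_percentiles(v),
               quantile(v, c(.1, .25, .5, .75, .9), names = FALSE) |>
                 setNames(c("10", "25", "50", "75", "90")))
})

test_that("glycemic_summary produces one coherent row per participant", {
  sim <- generate_cohort(cohort_config(n_participants = 2,
                                       n_sequence_ppt_first = 1),
                         seed = 11, period_days = 1)
  summ <- glycemic_summary(sim$bundle$traces, sim$bundle$meals)
  expect_equal(nrow(summ), 2L)
  expect_true(all(summ$glucose_cv >= 0))
  expect_true(all(summ$hours_above_140 >= summ$hours_above_180))
  expect_true(all(summ$n_meals == 8L)) # 4 slots x 2 periods x 1 day
})
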