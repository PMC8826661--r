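crossover_fixture <- function(ppt, med, n = length(ppt)) {
  ids <- sprintf("P%02d", seq_len(n))
  seqs <- rep(c("PPT-MED", "MED-PPT"), length.out = n)
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

test_that("paired crossover estimate is the mean within-person difference", {
  same <- crossover_fixture(ppt = c(50, 60, 70), med = c(50, 60, 70))
  res <- crossover_effect(same, "paired_t")
  expect_equal(res$estimate, 0)
  expect_equal(res$p_value, 1)

  set.seed(12)
  ppt <- rnorm(10, 40, 10); med <- rnorm(10, 60, 10)
  rec <- crossover_fixture(ppt, med)
  res2 <- crossover_effect(rec, "paired_t")
  expect_equal(res2$estimate, mean(ppt - med))
  expect_equal(res2$dispersion, sd(ppt - med))
  expect_equal(res2$p_value, t.test(ppt - med)$p.value)

  # swapping the diet labels flips the sign, p unchanged
  swapped <- rec
  swapped$diet <- ifelse(rec$diet == "PPT", "MED", "PPT")
  res3 <- crossover_effect(swapped, "paired_t")
  expect_equal(res3$estimate, -res2$estimate)
  expect_equal(res3$p_value, res2$p_value)
})

test_that("rank-based and mixed-model variants agree on direction", {
  set.seed(15)
  ppt <- rnorm(12, 40, 8); med <- ppt + 20 + rnorm(12, 0, 5)
  rec <- crossover_fixture(ppt, med)
  for (m in c("paired_t", "mann_whitney", "lmm", "lmm_period",
              "lmm_sequence")) {
    res <- crossover_effect(rec, m)
    expect_lt(res$estimate, 0)
    expect_lt(res$p_value, 0.05)
    expect_gte(res$p_value, 0)
  }
  # the first-period parallel check runs on half the data
  fp <- crossover_effect(rec, "first_period")
  expect_equal(fp$n, 12L)

  # the random-intercept LMM estimate equals the paired difference in a
  # balanced two-period design
  expect_equal(crossover_effect(rec, "lmm")$estimate,
               crossover_effect(rec, "paired_t")$estimate,
               tolerance = 1e-6)
})

test_that("participants missing a period are dropped with a warning", {
  rec <- crossover_fixture(ppt = c(40, 45, 50, 55), med = c(60, 62, 64, 66))
  rec <- rec[-1, ] # P01 loses the PPT period
  expect_warning(res <- crossover_effect(rec, "paired_t"), "missing a period")
  expect_equal(res$n, 3L)
})

test_that("crossover recovery: injected effect estimated without bias and covered", {
  cfg <- cohort_config() # n = 23, effect -20, within-person diff SD 16
  est <- replicate(50, NA_real_)
  covered <- logical(50)
  for (r in 1:50) {
    rec <- simulate_crossover(cfg, seed = 1000 + r)
    res <- crossover_effect(rec, "paired_t")
    est[r] <- res$estimate
    half <- qt(0.975, res$n - 1) * res$dispersion / sqrt(res$n)
    covered[r] <- abs(res$estimate - (-20)) <= half
  }
  expect_lt(abs(mean(est) - (-20)), 2)
  expect_gte(mean(covered), 0.9)
})

test_that("longitudinal change runs the one-sample test on T6 - T0", {
  panels <- tibble::tibble(
    participant_id = rep(sprintf("P%d", 1:5), 2),
    timepoint = rep(c("T0", "T6"), each = 5),
    hba1c = c(7, 7.2, 6.8, 7.5, 6.9, 7, 7.2, 6.8, 7.5, 6.9)
  )
  res <- longitudinal_change(panels, "hba1c")
  expect_equal(res$estimate, 0)
  expect_equal(res$p_value, 1)

  shifted <- panels
  shifted$hba1c[6:10] <- shifted$hba1c[1:5] - 0.4
  expect_equal(longitudinal_change(shifted, "hba1c")$estimate, -0.4)

  # t statistic against the closed form on a printed toy vector
  change <- c(-0.2, -0.6, 0.1, -0.4, -0.8)
  toy <- tibble::tibble(
    participant_id = rep(sprintf("P%d", 1:5), 2),
    timepoint = rep(c("T0", "T6"), each = 5),
    fpg = c(rep(150, 5), 150 + change)
  )
  res2 <- longitudinal_change(toy, "fpg")
  tstat <- mean(change) / (sd(change) / sqrt(5))
  expect_equal(res2$p_value, 2 * pt(-abs(tstat), df = 4))
  expect_equal(res2$estimate, mean(change))

  # rank-based alternative for skewed outcomes
  res3 <- longitudinal_change(toy, "fpg", test = "wilcoxon")
  expect_equal(res3$p_value, wilcox.test(change, mu = 0)$p.value)
})

test_that("HOMA-IR follows the mass-unit formula", {
  expect_equal(homa_ir(90, 4.5), 1)
  expect_equal(homa_ir(90, 9), 2 * homa_ir(90, 4.5))
  set.seed(2)
  fpg <- runif(10, 80, 200); ins <- runif(10, 2, 30)
  expect_equal(homa_ir(fpg, ins), fpg * ins / 405)
  expect_error(homa_ir(0, 5), "positive")
})

test_that("remission rate counts threshold boundaries correctly", {
  expect_equal(remission_rate(c(7, 7.5), c(6.2, 6.0))$fraction, 1)

  # baseline exactly 6.5 enters the denominator; end exactly 6.5 does not remit
  res <- remission_rate(c(6.5, 6.5), c(6.5, 6.4))
  expect_equal(res$denominator, 2L)
  expect_equal(res$numerator, 1L)

  # a 13-participant panel with 8 crossing below threshold
  base <- c(rep(7, 13), 6.0, 6.2, 6.4)
  end <- c(rep(6.2, 8), rep(6.8, 5), 6.0, 6.2, 6.4)
  res2 <- remission_rate(base, end)
  expect_equal(res2$denominator, 13L)
  expect_equal(res2$numerator, 8L)
  expect_equal(res2$fraction, 8 / 13)

  expect_true(is.na(remission_rate(c(6.0, 6.1), c(5.9, 6.0))$fraction))
})

test_that("adherence median split compares subgroup changes", {
  changes <- tibble::tibble(participant_id = sprintf("P%d", 1:6),
                            d_fpg = c(-20, -25, -18, -2, -5, 0))
  grades <- tibble::tibble(participant_id = sprintf("P%d", 1:6),
                           mean_grade = c(90, 92, 88, 70, 72, 84))
  res <- adherence_subgroup_compare(changes, grades)
  expect_equal(res$n_high, 3L) # median-valued participant joins the high group
  expect_equal(res$grade_median, 86)
  manual <- t.test(c(-20, -25, -18), c(-2, -5, 0))$p.value
  expect_equal(res$p_value, manual)

  same <- changes; same$d_fpg <- rep(1, 6)
  expect_equal(adherence_subgroup_compare(same, grades)$p_value, 1)

  flat_grades <- grades; flat_grades$mean_grade <- 80
  expect_error(adherence_subgroup_compare(changes, flat_grades), "degenerate")
})

test_that("intra- vs inter-person CV separates the variance components", {
  # all meals identical: both CVs zero
  same <- tibble::tibble(participant_id = rep(c("A", "B"), each = 3),
                         dominant_food = "bread", iauc = 50)
  res <- intra_inter_cv(same)
  expect_equal(res$intra_cv, 0)
  expect_equal(res$inter_cv, 0)

  # constant within person, different across: pure between-person signal
  between <- tibble::tibble(participant_id = rep(c("A", "B"), each = 3),
                            dominant_food = "bread",
                            iauc = rep(c(30, 90), each = 3))
  res2 <- intra_inter_cv(between)
  expect_equal(res2$intra_cv, 0)
  expect_gt(res2$inter_cv, 0)

  # person-level signal tau > noise sigma implies intra < inter (median
  # over seeds)
  sim_once <- function(seed, tau, sigma) {
    set.seed(seed)
    persons <- sprintf("P%d", 1:8)
    rows <- lapply(c("bread", "rice", "pasta"), function(food) {
      person_mean <- 60 + rnorm(8, 0, tau)
      tibble::tibble(participant_id = rep(persons, each = 4),
                     dominant_food = food,
                     iauc = pmax(rep(person_mean, each = 4) +
                                   rnorm(32, 0, sigma), 1))
    })
    r <- intra_inter_cv(dplyr::bind_rows(rows))
    r$intra_cv < r$inter_cv
  }
  ordering <- vapply(1:50, sim_once, logical(1), tau = 15, sigma = 5)
  expect_gt(mean(ordering), 0.5) # median ordering holds
})

test_that("p-values are valid and participant-order invariant", {
  set.seed(77)
  rec <- crossover_fixture(rnorm(8, 50, 10), rnorm(8, 55, 10))
  res <- crossover_effect(rec, "paired_t")
  shuffled <- rec[sample(nrow(rec)), ]
  res_shuffled <- crossover_effect(shuffled, "paired_t")
  expect_equal(res_shuffled$estimate, res$estimate)
  expect_equal(res_shuffled$p_value, res$p_value)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
})
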