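test_that("degenerate phenotype probabilities and seed determinism hold", {
  p <- cohort_params(n_fish = 10, phenotype_probs = c(1, 0, 0), seed = 1)
  co <- simulate_cohort(p, test_mixing)
  expect_length(co, 10)
  expect_true(all(vapply(co, `[[`, "", "phenotype") == "FWR"))
  expect_true(all(unlist(lapply(co, `[[`, "salinity")) < 0.5))

  co2 <- simulate_cohort(p, test_mixing)
  expect_identical(co, co2)
  expect_error(cohort_params(phenotype_probs = c(0.5, 0.2, 0.2)),
               "summing to 1")
})

test_that("phenotype draws follow the stated probabilities", {
  p <- cohort_params(n_fish = 285, phenotype_probs = c(0.12, 0.07, 0.81),
                     seed = 7)
  co <- simulate_cohort(p, test_mixing)
  counts <- table(factor(vapply(co, `[[`, "", "phenotype"),
                         c("FWR", "BWR", "SA")))
  for (i in 1:3) {
    lo <- qbinom(0.005, 285, p$phenotype_probs[i])
    hi <- qbinom(0.995, 285, p$phenotype_probs[i])
    expect_gte(counts[i], lo)
    expect_lte(counts[i], hi)
  }
})

test_that("every fish satisfies forward-consistency and salinity-side invariants", {
  p <- cohort_params(n_fish = 40, seed = 11)
  co <- simulate_cohort(p, test_mixing)
  for (f in co) {
    expect_identical(f$ratio, ratio_from_salinity(f$salinity, test_mixing))
    expect_length(f$salinity, f$age_at_capture + 1)
    expect_length(f$increments, f$age_at_capture)
    days <- 0:f$age_at_capture
    if (f$phenotype == "FWR") expect_true(all(f$salinity < 0.5))
    if (f$phenotype == "BWR") expect_true(all(f$salinity >= 0.5))
    if (f$phenotype == "SA") {
      expect_true(all(f$salinity[days < f$dispersal_age] < 0.5))
      expect_true(all(f$salinity[days >= f$dispersal_age] >= 0.5))
      expect_gte(f$dispersal_age, p$dispersal_truncation)
      expect_lte(f$dispersal_age, f$age_at_capture - p$dispersal_truncation)
    }
  }
})

test_that("phenotype proportions are unbiased across seeds", {
  probs <- c(FWR = 0.12, BWR = 0.07, SA = 0.81)
  # short lifespans keep 50 cohorts cheap; proportions are unaffected
  props <- t(vapply(1:50, function(s) {
    co <- simulate_cohort(cohort_params(n_fish = 285, seed = s,
                                        age_at_capture_range = c(60, 80)),
                          test_mixing)
    tab <- table(factor(vapply(co, `[[`, "", "phenotype"), names(probs)))
    as.numeric(tab) / 285
  }, numeric(3)))
  expect_lt(mean(abs(colMeans(props) - probs)), 0.02)
})

test_that("true chronologies follow the stated salinity shapes", {
  p0 <- cohort_params(salinity_jitter_sd = 0)
  set.seed(1)
  fwr <- simulate_true_chronology("FWR", 100, 0.1, params = p0,
                                  mixing = test_mixing)
  expect_equal(fwr$ratio, rep(ratio_from_salinity(0.1, test_mixing), 101))

  sa <- simulate_true_chronology("SA", 170, 0.1, 3, dispersal_age = 60,
                                 params = p0, mixing = test_mixing)
  expect_lt(sa$ratio[31], 0.7075)   # age 30
  expect_gt(sa$ratio[91], 0.7075)   # age 90
  expect_lt(sa$salinity[60], 0.5)   # age 59: still fresh
  expect_gte(sa$salinity[61], 0.5)  # age 60: crossing day

  bwr <- simulate_true_chronology("BWR", 100, 4, params = p0,
                                  mixing = test_mixing)
  expect_true(all(bwr$ratio > 0.7075))
  expect_error(simulate_true_chronology("SA", 100, 0.1, 3), "dispersal_age")
})

test_that("ablation scan geometry follows increments and scan speed", {
  fish <- list(fish_id = "G1", increments = rep(2, 100),
               ratio = rep(0.707, 101))
  run <- simulate_ablation_run(fish, ratio_noise_sd = 0, blank_s = 20)
  abl_t <- run$time_s[run$segment == "ablation"]
  expect_equal(max(run$time_s) - min(abl_t), 20, tolerance = 0.25 + 1e-9)
  expect_gte(max(run$time_s), 30)
  # 100 µm pre-core at 10 µm/s and 0.25 s cycles; the cycle landing exactly
  # on the core crossing counts as ablation
  expect_equal(sum(run$segment == "precore"), 100 / 10 / 0.25 - 1)
  expect_error(simulate_ablation_run(list(fish_id = "bad",
                                          increments = numeric(0),
                                          ratio = 0.707)),
               "increment")
})

test_that("injected gas blank is recovered by the reduction", {
  fish <- list(fish_id = "B1", increments = rep(2, 120),
               ratio = rep(0.707, 121))
  set.seed(2)
  run <- simulate_ablation_run(fish, ratio_noise_sd = 5e-4, blank_cps = 500)
  sub <- subtract_blank(run)
  est <- attr(sub, "blank_means")[["i88"]]
  blank_cycles <- run$i88[run$segment == "blank"]
  se <- sd(blank_cycles) / sqrt(length(blank_cycles))
  expect_lt(abs(est - 500), 3 * se + 1e-9)
})

test_that("maturity tables follow the logistic surface and the seed", {
  tab <- simulate_maturity_table(2000, coefficients = NULL, seed = 5)
  ci <- binom.test(sum(tab$late), 2000, 0.5)$conf.int
  expect_true(ci[1] < 0.5 && ci[2] > 0.5)
  expect_identical(tab$late, encode_stage(tab$stage))

  steep <- simulate_maturity_table(2000, c("jd_c" = 0.1), seed = 5)
  q <- quantile(steep$julian_date, c(0.25, 0.75))
  expect_gt(mean(steep$late[steep$julian_date >= q[2]]),
            mean(steep$late[steep$julian_date <= q[1]]))

  expect_identical(simulate_maturity_table(100, c("jd_c" = 0.05), seed = 9),
                   simulate_maturity_table(100, c("jd_c" = 0.05), seed = 9))
  expect_error(simulate_maturity_table(10, c(bogus = 1)), "unknown")
})
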