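test_that("blank subtraction removes the per-mass blank mean once", {
  run <- make_toy_run(i88 = 10000 / 0.1194, blank = 100)
  sub <- subtract_blank(run)
  expect_equal(mean(sub$i88[sub$segment == "ablation"]),
               10000 / 0.1194, tolerance = 1e-9)
  expect_error(subtract_blank(sub), "already")

  zero <- make_toy_run(blank = 0)
  sub0 <- subtract_blank(zero)
  expect_equal(sub0$i87, zero$i87)

  noblank <- as.data.frame(make_toy_run())
  noblank$segment[noblank$segment == "blank"] <- "precore"
  expect_error(ablation_run(noblank), "blank")
})

test_that("Rb correction subtracts the abundance-scaled mass-85 signal", {
  clean <- correct_rb(subtract_blank(make_toy_run(i85 = 0)))
  expect_equal(clean$i87, subtract_blank(make_toy_run(i85 = 0))$i87)

  # i86/i88 at the canonical ratio means beta = 0: pure abundance arithmetic
  run <- correct_rb(subtract_blank(make_toy_run(i85 = 1000)))
  raw <- subtract_blank(make_toy_run(i85 = 1000))
  abl <- run$segment == "ablation"
  expect_equal(raw$i87[abl] - run$i87[abl], rep(385.710, sum(abl)),
               tolerance = 1e-9)
  expect_error(correct_rb(make_toy_run()), "blank subtraction")

  # Rb-dominated signal: i85 large enough to drive mass 87 negative
  hot <- make_toy_run(i88 = 1000 / 0.1194, ratio = 0.707, i85 = 1e5)
  expect_error(correct_rb(subtract_blank(hot)), "Rb-dominated")
})

test_that("2% Rb contamination is corrected to within 2e-5", {
  fish <- list(fish_id = "RB", increments = rep(2, 120),
               ratio = rep(0.708, 121))
  run_rb <- simulate_ablation_run(fish, ratio_noise_sd = 0,
                                  rb_contamination = 0.02)
  run_clean <- simulate_ablation_run(fish, ratio_noise_sd = 0,
                                     rb_contamination = 0)
  r1 <- reduce_run(run_rb)
  r0 <- reduce_run(run_clean)
  expect_lt(max(abs(r1$ratio - r0$ratio)), 2e-5)
})

test_that("mass-bias normalization recovers the injected exponential bias", {
  # canonical 86/88 measured: beta = 0 and the ratio is untouched
  series <- normalize_mass_bias(correct_rb(subtract_blank(make_toy_run())))
  expect_equal(series$ratio, rep(0.707, nrow(series)), tolerance = 1e-12)

  fish <- list(fish_id = "MB", increments = rep(2, 120),
               ratio = rep(0.7082, 121))
  for (b in c(1.001, 1.002, 1.005)) {
    run <- simulate_ablation_run(fish, ratio_noise_sd = 0,
                                 mass_bias_per_amu = b, rb_contamination = 0)
    run <- correct_rb(subtract_blank(run))
    series <- normalize_mass_bias(run)
    expect_lt(max(abs(series$ratio - 0.7082)), 3e-5)
    # the fitted exponent reproduces the per-amu factor itself
    m86 <- 85.9092607; m88 <- 87.9056123
    b_hat <- exp(-attr(series, "mean_beta") * log(m86 / m88) / (m86 - m88))
    expect_lt(abs(b_hat - b) / b, 1e-3)
  }

  # dead mass-88 cycles are dropped and counted
  run <- correct_rb(subtract_blank(make_toy_run()))
  run$i88[20] <- 0
  series <- normalize_mass_bias(run)
  expect_equal(attr(series, "n_dropped"), 1L)
})

test_that("moving-window outlier rejection matches a brute-force reference", {
  expect_equal(nrow(reject_outliers(rep(0.707, 100))), 100)

  spiked <- rep(0.707, 100)
  spiked[40] <- 0.7120
  prof <- reject_outliers(spiked)
  expect_equal(attr(prof, "n_rejected"), 1L)
  expect_false(40 %in% prof$distance_um)

  short <- 0.707 + sin(1:45 / 7) * 1e-4
  expect_lte(nrow(reject_outliers(short)), 45)

  set.seed(42)
  for (rep_i in 1:10) {
    n <- sample(50:200, 1)
    x <- 0.707 + cumsum(rnorm(n, 0, 2e-5)) + rnorm(n, 0, 1e-4)
    flags <- oracle_outlier_flags(x)
    prof <- reject_outliers(x, max_reject_frac = 1)
    expect_equal(attr(prof, "n_rejected"), sum(flags))
    expect_equal(prof$distance_um, which(!flags))
  }
})

test_that("full reduction round-trips a noise-free run to 1e-5", {
  p0 <- cohort_params(n_fish = 1, phenotype_probs = c(0, 0, 1), seed = 3)
  co <- simulate_cohort(p0, test_mixing)
  fish <- co[[1]]
  run <- simulate_ablation_run(fish, ratio_noise_sd = 0,
                               mass_bias_per_amu = 1, rb_contamination = 0)
  prof <- reduce_run(run)
  truth <- approx(c(0, cumsum(fish$increments)), fish$ratio,
                  xout = prof$distance_um, rule = 2)$y
  expect_lt(max(abs(prof$ratio - truth)), 1e-5)
  expect_true(all(prof$ratio > 0.68 & prof$ratio < 0.72))
  expect_true(!is.unsorted(prof$distance_um))
})

test_that("default-noise cohorts lose few cycles to outlier rejection", {
  p <- cohort_params(n_fish = 10, seed = 21,
                     age_at_capture_range = c(180, 200))
  co <- simulate_cohort(p, test_mixing)
  set.seed(22)
  fracs <- vapply(co, function(f) {
    run <- simulate_ablation_run(f)
    prof <- reduce_run(run)
    lg <- attr(prof, "log")
    lg$n_rejected / lg$n_cycles
  }, 0)
  expect_lt(median(fracs), 0.05)
})
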