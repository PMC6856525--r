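test_that("gonad stages encode to the early/late binary", {
  expect_equal(encode_stage(c("I", "II", "III")), c(0L, 0L, 0L))
  expect_equal(encode_stage(c("IV", "V", "VI")), c(1L, 1L, 1L))
  expect_error(encode_stage("VII"), "unknown")
})

test_that("the null model intercept is exactly zero at perfect balance", {
  rec <- data.frame(sex = rep(c("F", "M"), 50),
                    region = rep(c("SP-S", "W-CD", "ND"), length.out = 100),
                    julian_date = rep(1:100), late = rep(0:1, each = 50))
  fit <- fit_logistic(rec, terms = "1")
  expect_lt(abs(coef(fit)[["(Intercept)"]]), 1e-10)
})

test_that("AICc, McFadden R2 and LR tests follow their definitions", {
  expect_equal(aicc(-10, 2, 20), 24 + 12 / 17, tolerance = 1e-9)
  expect_error(aicc(-10, 19, 20), "undefined")

  tab <- simulate_maturity_table(400, c("jd_c" = 0.05), seed = 1)
  full <- fit_logistic(tab)
  null <- fit_logistic(tab, terms = "1")
  m_self <- model_metrics(null, null)
  expect_equal(m_self$mcfadden_r2, 0)
  expect_equal(m_self$lr_chi2, 0)
  m <- model_metrics(full, null)
  expect_gt(m$AICc, m$AIC)
  expect_gt(m$mcfadden_r2, 0)
  expect_equal(m$lr_p,
               pchisq(m$lr_chi2, df = 11, lower.tail = FALSE))
})

test_that("intercept confidence intervals have nominal coverage under the null", {
  set.seed(20)
  covered <- 0L
  for (i in 1:100) {
    tab <- simulate_maturity_table(400, NULL, seed = 1000 + i)
    fit <- fit_logistic(tab)$glm
    est <- coef(fit)[["(Intercept)"]]
    se <- sqrt(diag(vcov(fit)))[["(Intercept)"]]
    if (abs(est) <= 1.96 * se) covered <- covered + 1L
  }
  expect_gte(covered, 93L)
})

test_that("a real three-way interaction wins the AICc comparison", {
  beta3 <- c("(Intercept)" = 0.2, "jd_c" = 0.02, "sexM" = 0.3,
             "jd_c:sexM:regionND" = 0.04)
  set.seed(21)
  wins <- 0L
  for (i in 1:100) {
    tab <- simulate_maturity_table(1000, beta3, seed = 2000 + i)
    full <- fit_logistic(tab)
    main <- fit_logistic(tab, terms = "jd_c + sex + region")
    null <- fit_logistic(tab, terms = "1")
    if (model_metrics(full, null)$AICc < model_metrics(main, null)$AICc)
      wins <- wins + 1L
  }
  expect_gte(wins, 90L)
})

test_that("coefficients of the full interaction model are recovered", {
  beta <- c("(Intercept)" = 0.2, "jd_c" = 0.02, "sexM" = 0.4,
            "regionW-CD" = 0.5, "regionND" = -0.3,
            "jd_c:sexM" = 0.01, "jd_c:regionW-CD" = -0.01,
            "jd_c:regionND" = 0.005, "sexM:regionW-CD" = 0.3,
            "sexM:regionND" = -0.2, "jd_c:sexM:regionW-CD" = -0.005,
            "jd_c:sexM:regionND" = 0.01)
  errs <- unlist(lapply(1:5, function(i) {
    tab <- simulate_maturity_table(2000, beta, seed = 3000 + i)
    b_hat <- coef(fit_logistic(tab))
    b_hat[names(beta)] - beta
  }))
  expect_lt(sqrt(mean(errs^2)), 0.15)
})

test_that("predicted curves are proper probabilities with the right shape", {
  flat <- fit_logistic(simulate_maturity_table(600, NULL, seed = 30),
                       terms = "1")
  # a null-generated, intercept-only model predicts near 0.5 everywhere
  p_flat <- predict_curves(flat)$p_late
  expect_true(all(abs(p_flat - 0.5) < 0.1))

  rising <- fit_logistic(simulate_maturity_table(2000, c("jd_c" = 0.06),
                                                 seed = 31))
  curves <- predict_curves(rising, julian_dates = seq(1, 151, 5))
  expect_true(all(curves$p_late > 0 & curves$p_late < 1))
  f_sps <- curves[curves$sex == "F" & curves$region == "SP-S", ]
  expect_true(all(diff(f_sps$p_late[order(f_sps$julian_date)]) >= 0))

  expect_error(predict_curves(rising,
                              grid = data.frame(julian_date = 10, sex = "F",
                                                region = "Delta")),
               "unseen")
})

test_that("centring choice changes coefficients but not fitted probabilities", {
  tab <- simulate_maturity_table(800, c("jd_c" = 0.03, "sexM" = 0.5),
                                 seed = 33)
  f76 <- fit_logistic(tab, jd_center = 76)
  f0 <- fit_logistic(tab, jd_center = 0)
  expect_false(isTRUE(all.equal(coef(f76)[["(Intercept)"]],
                                coef(f0)[["(Intercept)"]])))
  g <- expand.grid(julian_date = c(10, 76, 140), sex = c("F", "M"),
                   region = c("SP-S", "W-CD", "ND"),
                   stringsAsFactors = FALSE)
  expect_lt(max(abs(predict_curves(f76, grid = g)$p_late -
                      predict_curves(f0, grid = g)$p_late)), 1e-8)
})
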