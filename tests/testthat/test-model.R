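# Model pathway: coefficient sets, grids, analytic gradients, delta-method
# intervals, and the saturated fitter.

test_that("coefficient sets enforce the saturated parameterisation", {
  b <- table2_beta()
  expect_s3_class(table2_coefset(), "coef_set")
  expect_error(coef_set(c("lowMD", "highBMI", "smoker"), b[-4]),
               class = "rerin_incomplete_model")
  expect_error(coef_set(c("A", "B"), c(A = 1, B = 1, "A:B" = 0),
                        vcov = matrix(c(1, 0.5, 0, 0, 1, 0, 0, 0, 1), 3)),
               class = "rerin_incomplete_model")  # asymmetric vcov
  expect_error(coef_set(c("A", "B"), c(A = 1, B = 1, "A:B" = 0),
                        vcov = diag(c(1, -1, 1))),
               class = "rerin_incomplete_model")  # negative variance
  # '*' separators and scrambled term order are accepted
  cs <- coef_set(c("A", "B"), c("A*B" = 0.5, B = log(3), A = log(2)))
  expect_equal(unname(cs$beta), c(log(2), log(3), 0.5))
})

test_that("the grid exponentiates subset sums of coefficients", {
  g <- table2_grid()
  expect_equal(unname(g$rr["100"]), exp(0.36), tolerance = 1e-12)
  expect_equal(round(unname(g$rr["100"]), 2), 1.43)
  expect_equal(unname(g$rr["111"]), exp(0.36 + 0.29 + 0.41 - 0.27 - 0.23 - 0.24 + 0.92),
               tolerance = 1e-12)
  expect_equal(unname(g$rr["111"]), 3.456, tolerance = 1e-3)

  null <- coef_set(c("A", "B", "C"), rep(0, 7))
  expect_true(all(rr_grid_from_coefficients(null)$rr == 1))

  # round trip: log RR is the subset sum, for random coefficients
  set.seed(11)
  cs <- random_coefset(4)
  g4 <- rr_grid_from_coefficients(cs)
  for (p in names(g4$rr)) {
    idx <- rerin:::indices_from_pattern(p)
    subs <- Filter(function(s) all(s %in% idx), rerin:::subsets_canonical(4))
    expect_equal(log(g4$rr[[p]]),
                 sum(vapply(subs, function(s)
                   cs$beta[[rerin:::term_label(s, cs$factors)]], numeric(1))),
                 tolerance = 1e-12)
  }
})

test_that("analytic gradients agree with central finite differences", {
  # hand case: null 2-factor model.  d RERI2/d bA = RR_11 - RR_10 = 0 at the
  # null, so the gradient is (0, 0, 1); the finite-difference oracle agrees.
  cs0 <- coef_set(c("A", "B"), c(A = 0, B = 0, "A:B" = 0))
  expect_equal(unname(measure_gradient(cs0, measure_spec("RERI_top"))),
               c(0, 0, 1), tolerance = 1e-12)
  expect_equal(unname(measure_gradient(cs0, measure_spec("RERI_top"))),
               fd_gradient(cs0, measure_spec("RERI_top")), tolerance = 1e-6)
  # d RERI_2 / d beta_AB = RR_11
  cs1 <- coef_set(c("A", "B"), c(A = log(2), B = log(3), "A:B" = 0))
  expect_equal(measure_gradient(cs1, measure_spec("RERI_top"))[["A:B"]], 6,
               tolerance = 1e-12)

  set.seed(21)
  for (n in 2:4) {
    cs <- random_coefset(n)
    factors <- cs$factors
    specs <- c(rerin:::measure_specs_for(factors, "all"),
               list(measure_spec("MultIndex", factors),
                    measure_spec("RR", factors[1:2])))
    for (sp in specs) {
      g <- measure_gradient(cs, sp)
      fd <- fd_gradient(cs, sp)
      expect_equal(unname(g), fd, tolerance = 1e-6)
    }
  }
})

test_that("delta-method CIs reproduce printed Wald limits", {
  # HR interval: log-scale Wald, exponentiated
  vc <- diag(c(0.09, 0.08, 0.18, 0.12, 0.30, 0.29, 0.45)^2)
  cs <- table2_coefset(vc)
  hr <- delta_ci(cs, measure_spec("RR", "lowMD"))
  expect_equal(round(hr$estimate, 2), 1.43)
  expect_equal(round(hr$lower, 2), 1.20)
  expect_equal(round(hr$upper, 2), 1.71)

  # symmetric Wald on the RERI scale: se 1.01 around 1.98 gives (0.00, 3.96)
  m <- interaction_measure("RERI_top", c("A", "B", "C"), estimate = 1.98,
                           se = 1.01,
                           lower = 1.98 - qnorm(0.975) * 1.01,
                           upper = 1.98 + qnorm(0.975) * 1.01)
  expect_equal(round(m$lower, 2), 0.00)
  expect_equal(round(m$upper, 2), 3.96)

  # zero covariance collapses the interval onto the estimate
  cs0 <- coef_set(c("A", "B"), c(A = log(2), B = log(3), "A:B" = 0),
                  vcov = matrix(0, 3, 3))
  m0 <- delta_ci(cs0, measure_spec("RERI_top"))
  expect_equal(m0$se, 0)
  expect_equal(m0$lower, m0$estimate)
  expect_equal(m0$upper, m0$estimate)

  expect_error(delta_ci(table2_coefset(), measure_spec("RERI_top")),
               class = "rerin_missing_variance")
})

test_that("the saturated fitter recovers generating coefficients", {
  cfg <- scenario_config(family = "binomial", n_subjects = 50000,
                         n_replicates = 1, seed = 33)
  d <- generate_cohort(cfg, 1)
  f <- fit_saturated_model(d, cfg$factors, outcome = "y", family = "binomial")
  se <- sqrt(diag(vcov(f)))
  expect_true(all(abs(coef(f) - cfg$beta) < 3 * se))
  expect_s3_class(f, "reri_fit")
  expect_equal(nrow(f$measures), 8L)
})

test_that("formula interface splits exposures from covariates", {
  cfg <- scenario_config(family = "binomial", n_subjects = 30000,
                         n_replicates = 1, seed = 44, covariates = TRUE)
  d <- generate_cohort(cfg, 1)
  f <- reri(y ~ lowMD * highBMI * smoker + age + education, d,
            family = "binomial")
  expect_equal(f$factors, c("lowMD", "highBMI", "smoker"))
  expect_named(coef(f), rerin:::term_labels_canonical(f$factors))
  # covariates stay out of the grid but are retained in a side channel
  expect_true(any(grepl("age", names(f$side_coefficients))))
  expect_length(f$grid$rr, 8L)
  expect_error(reri(z ~ lowMD * highBMI, d, family = "binomial"),
               class = "rerin_column_error")
})

test_that("degenerate designs raise unidentifiable-cell errors", {
  cfg <- scenario_config(family = "binomial", n_subjects = 2000,
                         n_replicates = 1, seed = 55)
  d <- generate_cohort(cfg, 1)
  d2 <- d[!(d$lowMD == 1 & d$highBMI == 1 & d$smoker == 1), ]
  err <- tryCatch(fit_saturated_model(d2, cfg$factors, outcome = "y",
                                      family = "binomial"),
                  rerin_unidentifiable_cell = function(e) e)
  expect_s3_class(err, "rerin_unidentifiable_cell")
  expect_match(conditionMessage(err), "111")

  d3 <- d
  d3$lowMD <- d3$lowMD + 1L
  expect_error(fit_saturated_model(d3, cfg$factors, outcome = "y",
                                   family = "binomial"),
               class = "rerin_type_error")
})

test_that("logistic and Cox pathways agree for a rare outcome", {
  cfg_cox <- scenario_config(family = "cox", n_subjects = 60000,
                             n_replicates = 1, seed = 66, target_events = 0.05)
  d <- generate_cohort(cfg_cox, 1)
  f_cox <- fit_saturated_model(d, cfg_cox$factors, time = "time",
                               event = "event", family = "cox")
  f_log <- fit_saturated_model(d, cfg_cox$factors, outcome = "event",
                               family = "binomial")
  m_cox <- f_cox$measures$estimate
  m_log <- f_log$measures$estimate
  # same data, hazard vs odds scale: estimates agree within joint 3 SEs
  tol <- 3 * sqrt(f_cox$measures$se^2 + f_log$measures$se^2)
  expect_true(all(abs(m_cox - m_log) < pmax(tol, 0.1)))
})

test_that("protective exposures are refused unless reorientation is requested", {
  cfg <- scenario_config(n_factors = 2, factors = c("drugA", "B"),
                         prevalence = c(0.4, 0.3),
                         beta = c(drugA = -0.7, B = 0.4, "drugA:B" = 0),
                         family = "binomial", n_subjects = 20000,
                         n_replicates = 1, seed = 77)
  d <- generate_cohort(cfg, 1)
  expect_error(reri(y ~ drugA * B, d, family = "binomial"),
               class = "rerin_protective_factor")
  f <- suppressMessages(reri(y ~ drugA * B, d, family = "binomial",
                             reorient = TRUE))
  expect_true("no_drugA" %in% f$factors)
  expect_identical(nrow(check_risk_orientation(f$grid)), 0L)
})
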