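test_that("straight and quadratic curves have the expected acceleration", {
  grid <- seq(0, 50, 0.1)
  lin <- as_risk_curve(data.frame(tb = grid, mortality = 0.01 + 0.005 * grid))
  acc <- acceleration_curve(lin)
  expect_lt(max(abs(acc$acceleration)), 1e-6)
  infl <- find_inflections(acc)
  expect_true(is.na(infl$peak))
  expect_true(is.na(infl$valley))

  quad <- as_risk_curve(data.frame(tb = grid, mortality = 1e-4 * grid^2))
  acq <- acceleration_curve(quad)
  expect_equal(acq$acceleration, rep(2e-4, nrow(acq)), tolerance = 1e-4)
})

test_that("the logistic curve reproduces its closed-form second derivative", {
  crv <- logistic_test_curve()
  acc <- acceleration_curve(crv)
  s <- plogis((acc$tb - 15) / 3)
  closed_form <- 0.6 / 9 * s * (1 - s) * (1 - 2 * s)
  expect_lt(max(abs(acc$acceleration - closed_form)), 1e-4)

  infl <- find_inflections(acc)
  # analytic argmax of the logistic second derivative: 15 + 3*ln((3-sqrt(3))/(3+sqrt(3)))
  peak_exact <- 15 + 3 * log((3 - sqrt(3)) / (3 + sqrt(3)))
  expect_lt(abs(infl$peak - peak_exact), 0.1)
  expect_lt(abs(infl$valley - (30 - peak_exact)), 0.1)    # symmetric valley
  expect_gt(infl$valley, infl$peak)
})

test_that("analytic spline derivatives agree with finite differences", {
  # on an analytic input curve
  acc <- acceleration_curve(logistic_test_curve())
  expect_lt(attr(acc, "fd_discrepancy"), 1e-4)
  # and on a fitted adjusted curve
  cfg <- cohort_config("cirrhosis", n = 1500, seed = 8)
  an <- apply_exclusions(add_scores(simulate_cohort(cfg)))
  crv <- adjusted_risk_curve(fit_tb_gam(an, horizon = 90))
  expect_lt(attr(acceleration_curve(crv), "fd_discrepancy"), 1e-4)
  expect_error(acceleration_curve(crv[1:5, ]), class = "bilicurve_config_error")
})

test_that("the clinical cutoff inverts the smoothed 28-day curve at 15%", {
  crv <- logistic_test_curve()
  cc <- clinical_cutoff(crv, level = 0.15)
  expect_lt(abs(as.numeric(cc) - (15 - 3 * log(3))), 5e-3)
  expect_lt(abs(attr(cc, "mortality_at_cutoff") - 0.15), 1e-3)

  flat <- as_risk_curve(data.frame(tb = seq(0, 50, 0.1), mortality = 0.05),
                        horizon = 28)
  expect_true(is.na(clinical_cutoff(flat)))
  expect_error(clinical_cutoff(crv, level = 1.2), class = "bilicurve_config_error")
  expect_warning(clinical_cutoff(logistic_test_curve(horizon = 90)),
                 "28-day")
})

test_that("cutoff summaries count exceedance and read the curves", {
  cohort <- tibble::tibble(id = 1:10, tb = 1:10)
  grid <- seq(0, 50, 0.1)
  c28 <- as_risk_curve(data.frame(tb = grid, mortality = 0.002 * grid),
                       horizon = 28)
  c90 <- as_risk_curve(data.frame(tb = grid, mortality = 0.004 * grid),
                       horizon = 90)
  out <- summarize_cutoffs(cohort, c28, c90, c(mathematical = 5))
  expect_equal(out$frac_exceeding, 0.5)
  expect_equal(out$n_exceeding, 5L)
  expect_equal(out$mortality_28, 0.01, tolerance = 1e-6)
  expect_equal(out$mortality_90, 0.02, tolerance = 1e-6)
  # mean smoothed mortality among the patients above the cutoff (TB 6..10)
  expect_equal(out$mortality_90_above, 0.004 * 8, tolerance = 1e-6)

  high <- summarize_cutoffs(cohort, c28, c90, c(clinical = 60))
  expect_equal(high$frac_exceeding, 0)
  expect_true(is.na(high$mortality_28))
  expect_error(summarize_cutoffs(cohort, c28, c90, 5),
               class = "bilicurve_config_error")
})

test_that("exceedance at a recovered cutoff matches the TB-mixture tail", {
  cfg <- cohort_config("cirrhosis", n = 2592, seed = 12)
  an <- apply_exclusions(add_scores(simulate_cohort(cfg)))
  cut <- 14
  out <- summarize_cutoffs(an, NULL, NULL, c(mathematical = cut))
  # analytic tail of the 7-component mixture: uniform within (12,16],
  # full mass of (16,20] and the open top bin
  w <- cfg$tb_weights
  tail_prob <- w[5] * (16 - cut) / 4 + w[6] + w[7]
  expect_lt(abs(out$frac_exceeding - tail_prob), 0.05)
})
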