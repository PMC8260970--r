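test_that("identical configurations reproduce the cohort exactly", {
  cfg <- cohort_config("cirrhosis", n = 800, seed = 7)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 800)
  expect_named(c1, bilicurve:::cohort_columns())
})

test_that("cohort invariants hold: outcomes, grades, transplant days", {
  cfg <- cohort_config("cirrhosis", n = 3000, seed = 2)
  coh <- simulate_cohort(cfg)
  expect_true(all(coh$tb >= 0, na.rm = TRUE))
  expect_true(all(coh$he_grade %in% c(0, 2, 3, 4)))
  # death by day 28 implies death by day 90; counts are conserved
  expect_true(all(!coh$death_28 | coh$death_90))
  expect_lte(sum(coh$death_28), sum(coh$death_90))
  expect_lte(sum(coh$death_90), nrow(coh))
  expect_true(all(is.na(coh$lt_day) | coh$lt_day <= 90))
  expect_true(all(coh$lt_within_90 == !is.na(coh$lt_day)))
})

test_that("default calibration reproduces the published overall mortality", {
  cir <- simulate_cohort(cohort_config("cirrhosis", n = 2592, seed = 3))
  expect_lt(abs(mean(cir$death_90) - 0.166), 0.02)
  fib <- simulate_cohort(cohort_config("fibrosis", n = 940, seed = 3))
  expect_lt(abs(mean(fib$death_90) - 0.074), 0.02)
})

test_that("under a flat link, bin mortality is independent of TB", {
  cfg <- cohort_config("cirrhosis", n = 20000, seed = 5,
                       link = tb_link("flat"))
  coh <- simulate_cohort(cfg)
  coh$bin <- tb_bin(coh$tb)
  overall <- mean(coh$death_90)
  by_bin <- tapply(coh$death_90, coh$bin, mean)
  n_bin <- tapply(coh$death_90, coh$bin, length)
  se <- sqrt(overall * (1 - overall) / n_bin)
  expect_true(all(abs(by_bin - overall) < 4 * se))
})

test_that("empirical bin mortality agrees with the analytic oracle", {
  cfg <- cohort_config("cirrhosis", n = 50000, seed = 9)
  coh <- simulate_cohort(cfg)
  coh$bin <- tb_bin(coh$tb)
  emp <- tapply(coh$death_90, coh$bin, mean)
  n_emp <- tapply(coh$death_90, coh$bin, length)

  # independent Monte-Carlo draw from the same generative law
  x <- withr::with_seed(123457L, bilicurve:::draw_covariates(cfg, 50000))
  p <- 1 - exp(-cfg$baseline_hazard * 90 *
                 exp(bilicurve:::covariate_lp(x, cfg$beta) +
                       eval_link(cfg$link, x$tb)))
  bin_mc <- tb_bin(x$tb)
  oracle <- tapply(p, bin_mc, mean)
  n_mc <- tapply(p, bin_mc, length)

  se <- sqrt(oracle * (1 - oracle) / n_emp + tapply(p, bin_mc, stats::var) / n_mc)
  expect_true(all(abs(emp - oracle) < 3 * se + 1e-8))
})

test_that("the analytic curve reflects the link shape", {
  flat <- cohort_config("cirrhosis", n = 100, seed = 1, link = tb_link("flat"))
  cf <- true_risk_curve(flat, grid = seq(0, 50, 5), n_mc = 20000)
  expect_lt(diff(range(cf$mortality)), 1e-12)

  hin <- cohort_config("fibrosis", n = 100, seed = 1)
  ch <- true_risk_curve(hin, grid = seq(0, 12, 1), n_mc = 20000)
  expect_lt(diff(range(ch$mortality)), 1e-12)

  sig <- cohort_config("cirrhosis", n = 100, seed = 1)
  cs <- true_risk_curve(sig, grid = seq(0, 50, 1), n_mc = 20000)
  expect_true(all(diff(cs$mortality) >= 0))
})

test_that("configuration and oracle inputs are validated", {
  expect_error(cohort_config("cirrhosis", n = 0), class = "bilicurve_config_error")
  expect_error(cohort_config("cirrhosis", horizon_days = -1),
               class = "bilicurve_config_error")
  expect_error(cohort_config("cirrhosis", lt_rate = 1.5),
               class = "bilicurve_config_error")
  expect_error(cohort_config("cirrhosis", missingness = list(nosuch = 0.1)),
               class = "bilicurve_config_error")
  cfg <- cohort_config("cirrhosis", n = 10, seed = 1)
  expect_error(true_risk_curve(cfg, horizon = 0), class = "bilicurve_config_error")
  expect_error(true_risk_curve(cfg, grid = c(-1, 10)),
               class = "bilicurve_config_error")
})
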