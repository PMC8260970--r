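test_that("a flat link yields a nearly constant adjusted curve", {
  cfg <- cohort_config("cirrhosis", n = 5000, seed = 3, link = tb_link("flat"))
  an <- apply_exclusions(add_scores(simulate_cohort(cfg)))
  fit <- fit_tb_gam(an, horizon = 90)
  crv <- adjusted_risk_curve(fit)
  expect_lt(diff(range(crv$mortality)), 0.1)
  expect_lt(fit$df, 2.5)                        # smooth collapses toward linear
})

test_that("an S-shaped link is detected as non-linear", {
  cfg <- cohort_config("cirrhosis", n = 5000, seed = 4)
  an <- apply_exclusions(add_scores(simulate_cohort(cfg)))
  fit <- fit_tb_gam(an, horizon = 90)
  expect_gt(fit$df, 3)
  expect_gt(glance(fit)$n_events, 0)
})

test_that("degenerate outcomes and invalid grids are rejected", {
  coh <- simulate_cohort(cohort_config("cirrhosis", n = 300, seed = 3))
  coh$death_90 <- FALSE
  coh$death_28 <- FALSE
  coh$time_to_death <- 1000
  an <- apply_exclusions(add_scores(coh))
  expect_error(fit_tb_gam(an, horizon = 90), class = "bilicurve_no_events")

  cfg <- cohort_config("cirrhosis", n = 600, seed = 5)
  an <- apply_exclusions(add_scores(simulate_cohort(cfg)))
  fit <- fit_tb_gam(an, horizon = 90)
  expect_error(adjusted_risk_curve(fit, grid = c(-1, 10)),
               class = "bilicurve_config_error")
  expect_error(adjusted_risk_curve(fit, grid = c(0, 51)),
               class = "bilicurve_config_error")
  expect_error(fit_tb_gam(an, horizon = 45), class = "bilicurve_config_error")
})

test_that("curve probabilities stay in [0, 1], even on a two-point grid", {
  cfg <- cohort_config("cirrhosis", n = 800, seed = 6)
  an <- apply_exclusions(add_scores(simulate_cohort(cfg)))
  fit <- fit_tb_gam(an, horizon = 90)
  two <- adjusted_risk_curve(fit, grid = c(0, 50))
  expect_equal(nrow(two), 2)
  expect_true(all(two$mortality >= 0 & two$mortality <= 1))
  full <- adjusted_risk_curve(fit)
  expect_true(all(full$mortality >= 0 & full$mortality <= 1))
  expect_true(!is.unsorted(full$tb, strictly = TRUE))
})

test_that("marginal standardization matches patient-by-patient prediction", {
  cfg <- cohort_config("cirrhosis", n = 700, seed = 7)
  an <- apply_exclusions(add_scores(simulate_cohort(cfg)))
  fit <- fit_tb_gam(an, horizon = 90)
  grid <- c(0, 10, 25, 40, 50)
  crv <- adjusted_risk_curve(fit, grid = grid)
  direct <- vapply(grid, function(t) {
    d <- fit$data
    d$tb <- t
    mean(predict(fit$fit, newdata = d, type = "response"))
  }, numeric(1))
  expect_equal(crv$mortality, direct, tolerance = 1e-10)
})

test_that("curve error against the analytic oracle shrinks with sample size", {
  sup_err <- function(n, seed) {
    cfg <- cohort_config("cirrhosis", n = n, seed = seed)
    an <- apply_exclusions(add_scores(simulate_cohort(cfg)))
    fit <- fit_tb_gam(an, horizon = 90)
    crv <- adjusted_risk_curve(fit, grid = seq(0, 50, 0.5))
    tc <- true_risk_curve(cfg, grid = seq(0, 50, 0.5), horizon = 90)
    keep <- crv$tb <= 40   # region holding ~99% of the TB distribution
    max(abs(crv$mortality - tc$mortality)[keep])
  }
  small <- vapply(11:13, function(s) sup_err(2000, s), numeric(1))
  large <- vapply(11:13, function(s) sup_err(10000, s), numeric(1))
  expect_lt(mean(large), mean(small))
  expect_true(all(large < 0.08))
})

test_that("the 28-day curve lies below the 90-day curve", {
  cfg <- cohort_config("cirrhosis", n = 5000, seed = 4)
  an <- apply_exclusions(add_scores(simulate_cohort(cfg)))
  c28 <- adjusted_risk_curve(fit_tb_gam(an, horizon = 28))
  c90 <- adjusted_risk_curve(fit_tb_gam(an, horizon = 90))
  expect_true(all(c28$mortality <= c90$mortality + 0.01))
})
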