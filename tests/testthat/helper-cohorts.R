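# Fixture cohort whose TB-bin occupancies and death counts are set exactly:
# one row per patient, TB at the bin midpoint (25 for the open top bin),
# the first d28[i] patients of bin i dead by day 28, the first d90[i] dead
# by day 90.
bin_fixture_cohort <- function(n_bins, d90, d28 = rep(0L, 7)) {
  stopifnot(length(n_bins) == 7, all(d28 <= d90), all(d90 <= n_bins))
  mids <- c(1, 3.5, 6.5, 10, 14, 18, 25)
  rows <- lapply(seq_len(7), function(i) {
    n <- n_bins[i]
    if (n == 0) return(NULL)
    tibble::tibble(
      id = seq_len(n),
      tb = rep(mids[i], n),
      death_90 = seq_len(n) <= d90[i],
      death_28 = seq_len(n) <= d28[i]
    )
  })
  out <- dplyr::bind_rows(rows)
  out$id <- seq_len(nrow(out))
  out
}

# Tiny survival dataset with a binary covariate and distinct event times,
# for the brute-force partial-likelihood oracle.
toy_cox_cohort <- function() {
  tibble::tibble(
    time = c(3, 5, 7, 10, 14, 21, 30, 45),
    event = c(1, 1, 0, 1, 1, 0, 1, 0) == 1,
    x = c(1, 1, 0, 1, 0, 1, 0, 0)
  )
}

# Brute-force maximizer of the Cox partial log-likelihood for a single
# binary covariate over a beta grid (no ties in the event times).
brute_force_cox <- function(data, step = 1e-4, lim = 3) {
  betas <- seq(-lim, lim, by = step)
  ord <- order(data$time)
  data <- data[ord, ]
  ll <- numeric(length(betas))
  for (i in which(data$event)) {
    risk <- data$time >= data$time[i]
    n1 <- sum(data$x[risk] == 1)
    n0 <- sum(risk) - n1
    ll <- ll + betas * data$x[i] - log(n0 + n1 * exp(betas))
  }
  betas[which.max(ll)]
}

# The analytic logistic test curve p(TB) = 0.6 * sigmoid((TB - 15) / 3)
# sampled on the standard grid.
logistic_test_curve <- function(horizon = 28, step = 0.1) {
  grid <- seq(0, 50, by = step)
  as_risk_curve(data.frame(tb = grid, mortality = 0.6 * plogis((grid - 15) / 3)),
                horizon = horizon)
}

# A minimal hand-built patient record, valid for inclusion/grouping tests.
patient_record <- function(id = 1L, tb = 1, alt = 30, ast = 30,
                           ascites = FALSE, gi_bleeding = FALSE,
                           infection = FALSE, he_grade = 0L,
                           cirrhosis_status = "compensated",
                           prior_decompensation_flag = FALSE,
                           age = 50, platelets = 100, fib4 = NULL,
                           lt_within_90 = FALSE, lt_day = NA_integer_,
                           time_to_death = 200, death_90 = FALSE,
                           death_28 = FALSE) {
  rec <- tibble::tibble(
    id = id, age = age, sex = TRUE, etiology = "hbv",
    cirrhosis_status = cirrhosis_status,
    prior_decompensation_flag = prior_decompensation_flag,
    ascites = ascites, gi_bleeding = gi_bleeding, infection = infection,
    he_grade = he_grade, tb = tb, inr = 1.2, creatinine = 0.8, alt = alt,
    ast = ast, sodium = 138, albumin = 35, platelets = platelets,
    hemoglobin = 120, time_to_death = time_to_death, death_90 = death_90,
    death_28 = death_28, lt_within_90 = lt_within_90, lt_day = lt_day
  )
  if (!is.null(fib4)) rec$fib4 <- fib4
  rec
}
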