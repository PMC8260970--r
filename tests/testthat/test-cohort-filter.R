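test_that("inclusion criteria follow the decompensation/injury rules", {
  # jaundice alone (TB > 5) qualifies as acute decompensation
  r <- check_inclusion(patient_record(tb = 6))
  expect_true(r$included)
  expect_equal(r$inclusion_reason, "acute_decompensation")
  # ALT just above 3x ULN qualifies as acute liver injury
  r <- check_inclusion(patient_record(alt = 3.01 * 40))
  expect_true(r$included)
  expect_equal(r$inclusion_reason, "acute_liver_injury")
  # everything exactly at the limit does not qualify
  r <- check_inclusion(patient_record(tb = 1.2, alt = 40, ast = 40))
  expect_false(r$included)
  expect_equal(r$inclusion_reason, "none")
  # all relevant fields missing: indeterminate, not excluded
  rec <- patient_record()
  rec[c("ascites", "gi_bleeding", "infection", "tb", "alt", "ast")] <- NA
  rec$he_grade <- NA_integer_
  expect_true(is.na(check_inclusion(rec)$included))
})

test_that("group assignment handles decompensation history and FIB-4 boundary", {
  first_episode <- assign_group(patient_record(
    cirrhosis_status = "decompensated", prior_decompensation_flag = FALSE,
    fib4 = 2))
  expect_equal(first_episode$group, "cirrhosis_compensated")
  history <- assign_group(patient_record(
    cirrhosis_status = "decompensated", prior_decompensation_flag = TRUE,
    fib4 = 2))
  expect_equal(history$group, "cirrhosis_decompensated")
  expect_equal(assign_group(patient_record(cirrhosis_status = "none",
                                           fib4 = 1.2))$group,
               "excluded_mild_fibrosis")
  expect_equal(assign_group(patient_record(cirrhosis_status = "none",
                                           fib4 = 1.46))$group,
               "advanced_fibrosis")
  expect_equal(assign_group(patient_record(cirrhosis_status = "none",
                                           fib4 = NA_real_))$group,
               "excluded_missing_fib4")
})

test_that("exclusion cascade counts reconcile on a hand-built cohort", {
  coh <- dplyr::bind_rows(
    patient_record(id = 1, lt_within_90 = TRUE, lt_day = 45L),
    patient_record(id = 2, lt_within_90 = TRUE, lt_day = 3L),
    patient_record(id = 3, tb = NA_real_),
    lapply(4:10, function(i) patient_record(id = i, tb = 2))
  )
  analysis <- apply_exclusions(coh)
  rep <- filter_report(analysis)
  expect_equal(nrow(analysis), 7)
  expect_equal(rep$n_excluded_lt, 2)
  expect_equal(rep$n_excluded_missing_tb, 1)
  expect_equal(rep$n_excluded_fib4, 0)
  expect_equal(rep$n_input, 10)
  # dispositions partition the input
  expect_equal(nrow(rep$dispositions), 10)
  expect_equal(sum(rep$dispositions$disposition == "analysis"), 7)
  # LT precedes missing-TB: a transplanted patient with missing TB counts as LT
  both <- dplyr::bind_rows(
    patient_record(id = 1, lt_within_90 = TRUE, lt_day = 10L, tb = NA_real_),
    patient_record(id = 2))
  expect_equal(filter_report(apply_exclusions(both))$n_excluded_lt, 1)
})

test_that("filtering a filtered cohort removes nothing", {
  coh <- add_scores(simulate_cohort(cohort_config("fibrosis", n = 600, seed = 8)))
  once <- apply_exclusions(coh)
  twice <- apply_exclusions(once)
  expect_equal(nrow(twice), nrow(once))
  rep <- filter_report(once)
  expect_equal(rep$n_analysis,
               rep$n_cirrhosis_compensated + rep$n_cirrhosis_decompensated +
                 rep$n_advanced_fibrosis)
  expect_error(apply_exclusions(coh[0, ]), class = "bilicurve_config_error")
})
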