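#' Check the hospitalization inclusion criteria
#'
#' A patient qualifies when presenting with at least one acute
#' decompensation — overt ascites, gastrointestinal bleeding, overt hepatic
#' encephalopathy, bacterial infection, or jaundice (TB > 5 mg/dL) — or with
#' acute liver injury: ALT or AST above 3x the upper limit of normal, or TB
#' above 2x its upper limit of normal. When every field needed for the
#' decision is missing the result is indeterminate (`NA`), which is distinct
#' from not included.
#'
#' @param cohort A cohort data frame.
#' @param uln_alt_ast Upper limit of normal for ALT/AST, IU/L (default 40).
#' @param uln_tb Upper limit of normal for TB, mg/dL (default 1.2).
#' @return The cohort with logical `included` and character
#'   `inclusion_reason` (`"acute_decompensation"`, `"acute_liver_injury"`,
#'   `"none"`, or `NA` when indeterminate) appended.
#' @export
check_inclusion <- function(cohort, uln_alt_ast = 40, uln_tb = 1.2) {
  cohort <- as_tibble(cohort)
  f <- function(x) !is.na(x) & x            # missing counts as criterion absent
  ad <- f(cohort$ascites) | f(cohort$gi_bleeding) | f(cohort$infection) |
    (!is.na(cohort$he_grade) & cohort$he_grade > 0) |
    (!is.na(cohort$tb) & cohort$tb > 5)
  ali <- (!is.na(cohort$alt) & cohort$alt > 3 * uln_alt_ast) |
    (!is.na(cohort$ast) & cohort$ast > 3 * uln_alt_ast) |
    (!is.na(cohort$tb) & cohort$tb > 2 * uln_tb)
  all_missing <- is.na(cohort$ascites) & is.na(cohort$gi_bleeding) &
    is.na(cohort$infection) & is.na(cohort$he_grade) & is.na(cohort$tb) &
    is.na(cohort$alt) & is.na(cohort$ast)
  included <- ad | ali
  included[all_missing] <- NA
  reason <- dplyr::case_when(
    is.na(included) ~ NA_character_,
    ad ~ "acute_decompensation",
    ali ~ "acute_liver_injury",
    TRUE ~ "none"
  )
  mutate(cohort, included = included, inclusion_reason = reason)
}

#' Assign the analysis group of each patient
#'
#' Cirrhotic patients with a decompensation history at least one month old
#' form the decompensated-cirrhosis group; all other cirrhotic patients —
#' including those admitted for a first decompensation episode — form the
#' compensated-cirrhosis group. Non-cirrhotic patients with FIB-4 > 1.45
#' form the advanced-fibrosis group; FIB-4 at or below 1.45 marks at most
#' mild fibrosis and is excluded, as is a non-cirrhotic patient with missing
#' FIB-4.
#'
#' @param cohort A cohort data frame with `cirrhosis_status`,
#'   `prior_decompensation_flag` and (for non-cirrhotic rows) a `fib4`
#'   column, e.g. from [add_scores()].
#' @return The cohort with a `group` column: `"cirrhosis_compensated"`,
#'   `"cirrhosis_decompensated"`, `"advanced_fibrosis"`,
#'   `"excluded_mild_fibrosis"`, or `"excluded_missing_fib4"`.
#' @export
assign_group <- function(cohort) {
  cohort <- as_tibble(cohort)
  if (!"fib4" %in% names(cohort)) {
    abort("`cohort` needs a `fib4` column; run `add_scores()` first.",
          class = "bilicurve_config_error")
  }
  cirr <- cohort$cirrhosis_status %in% c("compensated", "decompensated")
  mutate(cohort, group = dplyr::case_when(
    cirr & cohort$prior_decompensation_flag ~ "cirrhosis_decompensated",
    cirr ~ "cirrhosis_compensated",
    is.na(cohort$fib4) ~ "excluded_missing_fib4",
    cohort$fib4 > 1.45 ~ "advanced_fibrosis",
    TRUE ~ "excluded_mild_fibrosis"
  ))
}

#' Apply the exclusion cascade and build the filter report
#'
#' Removes, in this fixed precedence order: patients transplanted within 90
#' days, patients with missing TB, and non-cirrhotic patients excluded by
#' the FIB-4 rule (mild fibrosis, or missing FIB-4). Each input row receives
#' exactly one disposition, so the counts reconcile with the input size.
#'
#' @param cohort A cohort data frame; a `group` column is added via
#'   [assign_group()] (and scores via [add_scores()]) if absent.
#' @return The analysis cohort (rows kept, with `group` and an
#'   `analysis_group` of `"cirrhosis"` or `"advanced_fibrosis"`), carrying a
#'   `filter_report` attribute; retrieve it with [filter_report()].
#' @export
apply_exclusions <- function(cohort) {
  cohort <- as_tibble(cohort)
  if (nrow(cohort) == 0) {
    abort("`cohort` is empty.", class = "bilicurve_config_error")
  }
  if (!"group" %in% names(cohort)) {
    if (!"fib4" %in% names(cohort)) cohort <- add_scores(cohort)
    cohort <- assign_group(cohort)
  }
  lt <- !is.na(cohort$lt_within_90) & cohort$lt_within_90 &
    !is.na(cohort$lt_day) & cohort$lt_day <= 90
  disposition <- dplyr::case_when(
    lt ~ "excluded_lt",
    is.na(cohort$tb) ~ "excluded_missing_tb",
    cohort$group == "excluded_mild_fibrosis" ~ "excluded_mild_fibrosis",
    cohort$group == "excluded_missing_fib4" ~ "excluded_missing_fib4",
    TRUE ~ "analysis"
  )
  keep <- disposition == "analysis"
  analysis <- cohort[keep, , drop = FALSE] |>
    mutate(analysis_group = if_else(.data$group == "advanced_fibrosis",
                                    "advanced_fibrosis", "cirrhosis"))
  report <- list(
    n_input = nrow(cohort),
    n_excluded_lt = sum(disposition == "excluded_lt"),
    n_excluded_missing_tb = sum(disposition == "excluded_missing_tb"),
    n_excluded_fib4 = sum(disposition == "excluded_mild_fibrosis"),
    n_excluded_missing_fib4 = sum(disposition == "excluded_missing_fib4"),
    n_analysis = sum(keep),
    n_cirrhosis_compensated = sum(analysis$group == "cirrhosis_compensated"),
    n_cirrhosis_decompensated = sum(analysis$group == "cirrhosis_decompensated"),
    n_advanced_fibrosis = sum(analysis$group == "advanced_fibrosis"),
    dispositions = tibble(id = cohort$id, disposition = disposition)
  )
  attr(analysis, "filter_report") <- report
  analysis
}

#' Retrieve the filter report of an analysis cohort
#'
#' @param cohort The output of [apply_exclusions()].
#' @return A list of exclusion counts, group sizes, and per-patient
#'   dispositions.
#' @export
filter_report <- function(cohort) {
  rep <- attr(cohort, "filter_report")
  if (is.null(rep)) {
    abort("no filter report attached; run `apply_exclusions()` first.",
          class = "bilicurve_config_error")
  }
  rep
}
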