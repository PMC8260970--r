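#' FIB-4 fibrosis index
#'
#' `FIB-4 = age * AST / (platelets * sqrt(ALT))`, with age in years, AST and
#' ALT in IU/L and platelets in 10^9/L. Values below 1.45 indicate at most
#' mild fibrosis and are used as an exclusion threshold for non-cirrhotic
#' patients.
#'
#' All score functions are vectorized and propagate `NA`; non-positive
#' (non-missing) inputs raise a domain error.
#'
#' @param age Age in years.
#' @param ast Aspartate aminotransferase, IU/L.
#' @param alt Alanine aminotransferase, IU/L.
#' @param platelets Platelet count, 10^9/L.
#' @return Unitless score.
#' @examples
#' fib4(50, 100, 100, 100) # 5
#' @export
fib4 <- function(age, ast, alt, platelets) {
  check_positive(age = age, ast = ast, alt = alt, platelets = platelets)
  age * ast / (platelets * sqrt(alt))
}

#' MELD score
#'
#' `MELD = 3.78 ln(TB) + 11.2 ln(INR) + 9.57 ln(creatinine) + 6.43`, with the
#' UNOS conventions: each input below 1.0 is clamped to 1.0 before the
#' logarithm and creatinine is capped at 4.0 mg/dL.
#'
#' @param tb Total bilirubin, mg/dL.
#' @param inr International normalized ratio.
#' @param creatinine Serum creatinine, mg/dL.
#' @return MELD points.
#' @examples
#' meld(1, 1, 1) # 6.43
#' @export
meld <- function(tb, inr, creatinine) {
  check_positive(tb = tb, inr = inr, creatinine = creatinine)
  tb <- pmax(tb, 1)
  inr <- pmax(inr, 1)
  creatinine <- pmin(pmax(creatinine, 1), 4)
  3.78 * log(tb) + 11.2 * log(inr) + 9.57 * log(creatinine) + 6.43
}

#' MELD-Na score
#'
#' `MELD-Na = MELD + 1.32 (137 - Na) - 0.033 MELD (137 - Na)`, with sodium
#' clipped to \[125, 137\] mmol/L; sodium at or above 137 leaves MELD
#' unchanged.
#'
#' @param meld MELD points.
#' @param sodium Serum sodium, mmol/L.
#' @return MELD-Na points.
#' @export
meld_na <- function(meld, sodium) {
  if (any(meld < 0, na.rm = TRUE)) {
    abort("`meld` must be >= 0.", class = "bilicurve_domain_error")
  }
  na <- pmin(pmax(sodium, 125), 137)
  meld + 1.32 * (137 - na) - 0.033 * meld * (137 - na)
}

#' Child-Turcotte-Pugh score
#'
#' Sum of five 1-3-point components: total bilirubin (< 2 / 2-3 / > 3
#' mg/dL), albumin (> 35 / 28-35 / < 28 g/L), INR (< 1.7 / 1.7-2.3 / > 2.3),
#' ascites (none / mild / moderate-severe), and hepatic encephalopathy.
#' The cohort grades HE as not overt (0) or overt grade 2/3/4; grade 0 scores
#' 1 point, grade 2 scores 2 points (grade I-II band), grades 3-4 score 3
#' points.
#'
#' @param tb Total bilirubin, mg/dL.
#' @param albumin Serum albumin, g/L.
#' @param inr International normalized ratio.
#' @param ascites_grade `"none"`, `"mild"`, or `"moderate-severe"`.
#' @param he_grade 0 (not overt), 2, 3, or 4.
#' @return CTP points, in \[5, 15\].
#' @export
ctp <- function(tb, albumin, inr, ascites_grade = "none", he_grade = 0) {
  check_positive(tb = tb, albumin = albumin, inr = inr)
  ok_asc <- ascites_grade %in% c("none", "mild", "moderate-severe")
  if (any(!ok_asc & !is.na(ascites_grade))) {
    abort("unknown `ascites_grade` category.", class = "bilicurve_domain_error")
  }
  ok_he <- he_grade %in% c(0, 2, 3, 4)
  if (any(!ok_he & !is.na(he_grade))) {
    abort("`he_grade` must be one of 0, 2, 3, 4.", class = "bilicurve_domain_error")
  }
  tb_pts <- 1 + (tb >= 2) + (tb > 3)
  alb_pts <- 1 + (albumin <= 35) + (albumin < 28)
  inr_pts <- 1 + (inr >= 1.7) + (inr > 2.3)
  asc_pts <- 1 + (ascites_grade != "none") + (ascites_grade == "moderate-severe")
  he_pts <- 1 + (he_grade >= 2) + (he_grade >= 3)
  tb_pts + alb_pts + inr_pts + asc_pts + he_pts
}

#' Assign the seven-bin total-bilirubin category
#'
#' Bins are upper-inclusive half-open intervals `(lo, hi]` over
#' `{2, 5, 8, 12, 16, 20}` mg/dL: `0-2`, `2-5`, `5-8`, `8-12`, `12-16`,
#' `16-20`, `>20`; a TB of 0 maps to `0-2` and each edge maps to the
#' lower-labeled bin (e.g. 12 to `8-12`).
#'
#' @param tb Total bilirubin, mg/dL (>= 0).
#' @return Factor with the seven bin levels (lowest bin first).
#' @examples
#' tb_bin(c(0, 2, 12, 50))
#' @export
tb_bin <- function(tb) {
  if (any(tb < 0, na.rm = TRUE)) {
    abort("`tb` must be >= 0.", class = "bilicurve_domain_error")
  }
  idx <- 1L + rowSums(outer(tb, tb_bin_edges(), ">"))
  factor(tb_bin_labels()[idx], levels = tb_bin_labels())
}

#' Append severity scores and TB bin to a cohort
#'
#' Adds `fib4`, `meld`, `meld_na`, `ctp` and `tb_bin` columns computed from
#' the cohort's laboratory values. The binary `ascites` flag is mapped to the
#' CTP `"mild"` ascites category when present. Rows with a missing component
#' get a missing score.
#'
#' @param cohort A cohort data frame (see [simulate_cohort()] for the schema).
#' @return The cohort tibble with five score columns appended.
#' @export
add_scores <- function(cohort) {
  cohort <- as_tibble(cohort)
  asc <- if_else(cohort$ascites %in% TRUE, "mild", "none")
  cohort |>
    mutate(
      fib4 = na_safe(fib4, .data$age, .data$ast, .data$alt, .data$platelets),
      meld = na_safe(meld, .data$tb, .data$inr, .data$creatinine),
      meld_na = na_safe(meld_na, .data$meld, .data$sodium),
      ctp = na_safe(ctp, .data$tb, .data$albumin, .data$inr, asc,
                    .data$he_grade),
      tb_bin = tb_bin(.data$tb)
    )
}

# apply a score function on complete rows only, NA elsewhere
na_safe <- function(f, ...) {
  args <- list(...)
  ok <- Reduce(`&`, lapply(args, function(a) !is.na(a)))
  out <- rep(NA_real_, length(ok))
  if (any(ok)) out[ok] <- do.call(f, lapply(args, function(a) a[ok]))
  out
}

check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    if (any(args[[nm]] <= 0, na.rm = TRUE)) {
      abort(sprintf("`%s` must be > 0.", nm), class = "bilicurve_domain_error")
    }
  }
  invisible(NULL)
}
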