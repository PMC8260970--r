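# shared covariate preparation for the Cox and GAM adjustment sets:
# age, sex, etiology (HBV reference), ascites, GI bleeding, bacterial
# infection, HE grade (not-overt reference), INR, creatinine, ln(ALT), sodium
prepare_model_data <- function(cohort, horizon = 90) {
  cohort |>
    mutate(
      etiology = factor(.data$etiology, levels = c("hbv", "alcoholic", "other")),
      he_factor = factor(.data$he_grade, levels = c(0, 2, 3, 4)),
      ln_alt = log(.data$alt),
      time = pmin(.data$time_to_death, horizon),
      event = if (horizon <= 28) .data$death_28 else .data$death_90
    )
}

adjustment_terms <- function(include_gi_bleeding = TRUE) {
  terms <- c("age", "sex", "etiology", "ascites", "gi_bleeding", "infection",
             "he_factor", "inr", "creatinine", "ln_alt", "sodium")
  if (!include_gi_bleeding) terms <- setdiff(terms, "gi_bleeding")
  terms
}

model_vars <- function(terms) {
  sub("^ln_alt$", "alt", sub("^he_factor$", "he_grade", terms))
}

subset_group <- function(cohort, group) {
  if (is.null(group)) return(cohort)
  group <- match.arg(group, c("cirrhosis", "advanced_fibrosis"))
  if (!"analysis_group" %in% names(cohort)) {
    abort("`cohort` has no `analysis_group`; run `apply_exclusions()` or omit `group`.",
          class = "bilicurve_config_error")
  }
  filter(cohort, .data$analysis_group == .env$group)
}

# GI bleeding stays in the adjustment set only for the cirrhosis group (and
# only when it varies in the data)
use_gi_bleeding <- function(cohort, group) {
  if (identical(group, "advanced_fibrosis")) return(FALSE)
  if (is.null(group) && "analysis_group" %in% names(cohort) &&
      all(cohort$analysis_group == "advanced_fibrosis")) {
    return(FALSE)
  }
  gb <- cohort$gi_bleeding
  length(unique(gb[!is.na(gb)])) > 1
}

#' Multivariable Cox model of total bilirubin on transplantation-free
#' mortality
#'
#' Fits a Cox proportional-hazards model (Efron tie handling) of 90-day
#' transplantation-free mortality on TB, either per mg/dL (`"continuous"`)
#' or across the seven TB bins with the lowest bin (`0-2` mg/dL) as
#' reference (`"categorical"`). The adjusted model controls for age, sex,
#' etiology, overt ascites, gastrointestinal bleeding (cirrhosis group
#' only), bacterial infection, HE grade, INR, creatinine, ln(ALT), and serum
#' sodium; `adjusted = FALSE` drops all confounders. Rows with a missing
#' model variable are dropped (complete-case analysis) and the number used
#' is recorded.
#'
#' @param cohort An analysis cohort (e.g. from [apply_exclusions()]).
#' @param exposure `"continuous"` or `"categorical"`.
#' @param adjusted Include the confounder set? Default `TRUE`.
#' @param group Optional `"cirrhosis"` or `"advanced_fibrosis"` to restrict
#'   an `analysis_group`-labelled cohort.
#' @param horizon Follow-up horizon in days (default 90).
#' @return A `tb_cox` object; see [tidy.tb_cox()] and [glance.tb_cox()].
#' @examples
#' cfg <- cohort_config("cirrhosis", n = 400, seed = 7,
#'                      link = tb_link("linear", slope = 0.06))
#' fit <- simulate_cohort(cfg) |> apply_exclusions() |> fit_tb_cox()
#' tidy(fit)
#' @export
fit_tb_cox <- function(cohort, exposure = c("continuous", "categorical"),
                       adjusted = TRUE, group = NULL, horizon = 90) {
  exposure <- match.arg(exposure)
  cohort <- subset_group(as_tibble(cohort), group)
  gi <- use_gi_bleeding(cohort, group)
  terms <- if (adjusted) adjustment_terms(gi) else character(0)
  need <- c("tb", "time_to_death", "death_90", model_vars(terms))
  cc <- complete.cases(cohort[, intersect(need, names(cohort))])
  data <- prepare_model_data(cohort[cc, , drop = FALSE], horizon)

  n_events <- sum(data$event)
  if (n_events == 0) {
    abort("no events in the cohort; cannot fit a Cox model.",
          class = "bilicurve_no_events")
  }
  if (n_events < 2) {
    abort("fewer than 2 events; cannot fit a Cox model.",
          class = "bilicurve_no_events")
  }

  if (exposure == "categorical") {
    full <- tb_bin(data$tb)
    empty <- setdiff(tb_bin_labels(), unique(as.character(full)))
    data$tb_expo <- droplevels(full)
    if (length(empty)) {
      warn(paste0("empty TB bin(s) dropped: ", paste(empty, collapse = ", ")))
    }
    expo_term <- "tb_expo"
  } else {
    data$tb_expo <- data$tb
    expo_term <- "tb_expo"
  }

  rhs <- paste(c(expo_term, terms), collapse = " + ")
  n_terms <- length(terms) + if (exposure == "categorical") {
    nlevels(data$tb_expo) - 1L
  } else {
    1L
  }
  if (nrow(data) < 10 * n_terms) {
    warn(sprintf("only %d complete cases for %d model terms (< 10 per term).",
                 nrow(data), n_terms))
  }

  fml <- as.formula(paste("survival::Surv(time, event) ~", rhs))
  fit <- survival::coxph(fml, data = data, ties = "efron")
  if (!is.null(fit$info) && any(grepl("did not converge", fit$info))) {
    abort("Cox model did not converge.", class = "bilicurve_fit_error")
  }

  sm <- summary(fit)
  ci <- suppressMessages(confint(fit))
  tab <- tibble(
    term = pretty_terms(rownames(sm$coefficients), exposure),
    estimate = unname(sm$coefficients[, "coef"]),
    std.error = unname(sm$coefficients[, "se(coef)"]),
    statistic = unname(sm$coefficients[, "z"]),
    p.value = unname(sm$coefficients[, "Pr(>|z|)"]),
    hr = unname(exp(sm$coefficients[, "coef"])),
    conf.low = unname(exp(ci[, 1])),
    conf.high = unname(exp(ci[, 2]))
  )
  structure(
    list(table = tab, fit = fit, exposure = exposure, adjusted = adjusted,
         reference = if (exposure == "categorical") tb_bin_labels()[1] else NULL,
         n_used = nrow(data), n_events = n_events,
         concordance = unname(sm$concordance["C"]), aic = AIC(fit)),
    class = "tb_cox"
  )
}

pretty_terms <- function(terms, exposure) {
  terms <- sub("^tb_expo$", "tb", terms)
  sub("^tb_expo", "tb_bin", terms)
}

#' Ordinal trend test across TB bins
#'
#' Refits the (adjusted) Cox model with the TB bin entered as a single
#' ordinal covariate (1-7) and returns the Wald p-value of its coefficient —
#' the "p for trend" of the binned analysis.
#'
#' @inheritParams fit_tb_cox
#' @return A list with `p.value`, `estimate` (log HR per bin step), and
#'   `n_used`.
#' @export
tb_trend_test <- function(cohort, adjusted = TRUE, group = NULL, horizon = 90) {
  cohort <- subset_group(as_tibble(cohort), group)
  gi <- use_gi_bleeding(cohort, group)
  terms <- if (adjusted) adjustment_terms(gi) else character(0)
  need <- c("tb", "time_to_death", "death_90", model_vars(terms))
  cc <- complete.cases(cohort[, intersect(need, names(cohort))])
  data <- prepare_model_data(cohort[cc, , drop = FALSE], horizon)
  data$tb_ordinal <- as.integer(tb_bin(data$tb))
  if (length(unique(data$tb_ordinal)) < 2) {
    abort("all patients fall in a single TB bin; no ordinal variation.",
          class = "bilicurve_config_error")
  }
  if (sum(data$event) < 2) {
    abort("fewer than 2 events; cannot fit a Cox model.",
          class = "bilicurve_no_events")
  }
  fml <- as.formula(paste("survival::Surv(time, event) ~",
                          paste(c("tb_ordinal", terms), collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = "efron")
  sm <- summary(fit)$coefficients
  list(p.value = unname(sm["tb_ordinal", "Pr(>|z|)"]),
       estimate = unname(sm["tb_ordinal", "coef"]),
       n_used = nrow(data))
}

#' @describeIn fit_tb_cox Tidy the coefficient table (one row per term, with
#'   `hr` and Wald 95% CI bounds on the hazard-ratio scale).
#' @param x A `tb_cox` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.tb_cox <- function(x, ...) x$table

#' @describeIn fit_tb_cox One-row model summary.
#' @exportS3Method generics::glance
glance.tb_cox <- function(x, ...) {
  tibble(n_used = x$n_used, n_events = x$n_events, exposure = x$exposure,
         adjusted = x$adjusted, concordance = x$concordance, AIC = x$aic)
}

#' @export
print.tb_cox <- function(x, ...) {
  cat(sprintf("<tb_cox: %s TB exposure, %s; %d patients, %d events>\n",
              x$exposure, if (x$adjusted) "adjusted" else "unadjusted",
              x$n_used, x$n_events))
  print(x$table)
  invisible(x)
}
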