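#' Fit the confounder-adjusted spline GAM of death by a horizon
#'
#' Fits a binomial-logit generalized additive model of the 28- or 90-day
#' death indicator on a penalized cubic regression spline of TB plus the
#' same confounder set as [fit_tb_cox()]. The smoothing parameter is
#' selected by restricted maximum likelihood (REML), the stable default for
#' penalized regression smoothers; prediction-error criteria (GCV/UBRE/AIC)
#' are prone to occasional catastrophic undersmoothing on cohorts of this
#' size. A binary outcome model is justified here because
#' every patient completes the 90-day follow-up and transplanted patients
#' are excluded, so the indicator is fully observed.
#'
#' @param cohort An analysis cohort.
#' @param horizon 28 or 90 (days).
#' @param basis_dim Dimension of the TB spline basis (knots spread evenly
#'   over the TB range; default 11, must be >= 4).
#' @param gamma Degrees-of-freedom inflation of the smoothing criterion
#'   (1 = plain REML).
#' @param group Optional `"cirrhosis"` or `"advanced_fibrosis"` restriction.
#' @param adjusted Include the confounder set? Default `TRUE`.
#' @return A `tb_gam` object: the `mgcv::gam` fit plus the effective df of
#'   the TB smooth, horizon, and the complete-case data used.
#' @export
fit_tb_gam <- function(cohort, horizon = 90, basis_dim = 11, gamma = 1,
                       group = NULL, adjusted = TRUE) {
  if (!horizon %in% c(28, 90)) {
    abort("`horizon` must be 28 or 90.", class = "bilicurve_config_error")
  }
  if (basis_dim < 4) {
    abort("spline basis dimension must be >= 4.", class = "bilicurve_config_error")
  }
  cohort <- subset_group(as_tibble(cohort), group)
  gi <- use_gi_bleeding(cohort, group)
  terms <- if (adjusted) adjustment_terms(gi) else character(0)
  need <- c("tb", if (horizon == 28) "death_28" else "death_90",
            model_vars(terms))
  cc <- complete.cases(cohort[, intersect(need, names(cohort))])
  data <- prepare_model_data(cohort[cc, , drop = FALSE], horizon)
  data$y <- as.integer(if (horizon == 28) data$death_28 else data$death_90)

  if (nrow(data) < 50) {
    abort("fewer than 50 complete cases; cannot fit the GAM.",
          class = "bilicurve_config_error")
  }
  if (length(unique(data$y)) < 2) {
    abort("outcome has a single class (no deaths or no survivors).",
          class = "bilicurve_no_events")
  }

  # knots spread evenly over the reporting range [0, 50] (extended if the
  # data exceed it) so the basis has uniform resolution along TB rather than
  # concentrating flexibility where patients cluster
  knot_range <- c(min(0, min(data$tb)), max(50, max(data$tb)))
  kn <- list(tb = seq(knot_range[1], knot_range[2], length.out = basis_dim))
  fml <- as.formula(paste(
    c(sprintf("y ~ s(tb, k = %d, bs = 'cr')", basis_dim), terms),
    collapse = " + "))
  fit <- mgcv::gam(fml, family = stats::binomial(), data = data, knots = kn,
                   method = "REML", gamma = gamma)
  if (!fit$converged || !is.finite(AIC(fit))) {
    abort("GAM fit did not converge.", class = "bilicurve_fit_error")
  }
  structure(
    list(fit = fit, df = unname(summary(fit)$edf),
         horizon = horizon, adjusted = adjusted, terms = terms,
         n_fit = nrow(data), n_events = sum(data$y), data = data),
    class = "tb_gam"
  )
}

#' @describeIn fit_tb_gam One-row summary (horizon, effective df of the TB
#'   smooth, AIC, deviance, n, events).
#' @param x A `tb_gam` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.tb_gam <- function(x, ...) {
  tibble(horizon = x$horizon, edf_tb = x$df, AIC = AIC(x$fit),
         deviance = stats::deviance(x$fit), n_fit = x$n_fit,
         n_events = x$n_events)
}

#' @export
print.tb_gam <- function(x, ...) {
  cat(sprintf(
    "<tb_gam: %d-day mortality, TB smooth edf = %.1f, n = %d, events = %d>\n",
    x$horizon, x$df, x$n_fit, x$n_events))
  invisible(x)
}

new_risk_curve <- function(tb, mortality, horizon, n_fit, df = NA_integer_,
                           source = "gam") {
  out <- tibble(tb = tb, mortality = mortality)
  class(out) <- c("tb_risk_curve", class(out))
  attr(out, "horizon") <- horizon
  attr(out, "n_fit") <- n_fit
  attr(out, "df") <- df
  attr(out, "source") <- source
  out
}

#' Confounder-adjusted TB-mortality correlation curve
#'
#' Builds the adjusted mortality curve by marginal standardization
#' (g-computation): for each TB value on the grid, every patient's TB is set
#' to that value while their observed confounders are kept, and the model's
#' predicted death probabilities are averaged over the complete-case cohort.
#' Because the linear predictor is additive, the TB spline contribution is
#' computed once per grid point and shifted across patients, which is exact
#' and fast.
#'
#' @param fit A [fit_tb_gam()] object.
#' @param grid TB grid in mg/dL within \[0, 50\] (default step 0.1).
#' @param newdata Optional standardization population (defaults to the data
#'   the GAM was fitted on).
#' @return A `tb_risk_curve` tibble with columns `tb`, `mortality` and
#'   attributes `horizon`, `n_fit`, `df`.
#' @export
adjusted_risk_curve <- function(fit, grid = seq(0, 50, by = 0.1),
                                newdata = NULL) {
  stopifnot(inherits(fit, "tb_gam"))
  if (any(grid < 0) || any(grid > 50)) {
    abort("`grid` must lie within [0, 50].", class = "bilicurve_config_error")
  }
  grid <- sort(unique(grid))
  data <- newdata %||% fit$data
  # per-patient linear predictor with TB anchored at the grid's first value
  base <- data
  base$tb <- grid[1]
  lp0 <- as.numeric(predict(fit$fit, newdata = base, type = "link"))
  # TB-spline offset per grid value, evaluated on a single reference row
  ref <- data[rep(1L, length(grid)), , drop = FALSE]
  ref$tb <- grid
  ref0 <- data[rep(1L, length(grid)), , drop = FALSE]
  ref0$tb <- grid[1]
  delta <- as.numeric(predict(fit$fit, newdata = ref, type = "link")) -
    as.numeric(predict(fit$fit, newdata = ref0, type = "link"))
  mort <- vapply(delta, function(d) mean(plogis(lp0 + d)), numeric(1))
  new_risk_curve(grid, mort, horizon = fit$horizon, n_fit = nrow(data),
                 df = fit$df)
}

# cubic smoothing spline refit of a (grid, mortality) curve; the common
# smoother behind differentiation, root finding, and curve evaluation
curve_spline <- function(curve, df = NULL) {
  stopifnot(inherits(curve, "tb_risk_curve"))
  if (nrow(curve) < 10) {
    abort("curve has fewer than 10 grid points.", class = "bilicurve_config_error")
  }
  if (is.null(df)) {
    smooth.spline(curve$tb, curve$mortality, all.knots = TRUE)
  } else {
    smooth.spline(curve$tb, curve$mortality, df = df, all.knots = TRUE)
  }
}

#' Evaluate the smoothed adjusted-mortality curve at TB values
#'
#' Refits the cubic smoothing spline used throughout the cutoff stage and
#' evaluates it at `tb`.
#'
#' @param curve A `tb_risk_curve`.
#' @param tb TB values (mg/dL).
#' @param df Optional smoothing-spline degrees of freedom (default:
#'   generalized cross-validation).
#' @return Numeric vector of mortality probabilities.
#' @export
curve_value_at <- function(curve, tb, df = NULL) {
  ss <- curve_spline(curve, df = df)
  as.numeric(predict(ss, x = tb)$y)
}

#' Construct a risk curve from a data frame
#'
#' Wraps a `(tb, mortality)` table — e.g. a curve read back from CSV, or an
#' externally computed curve — as a `tb_risk_curve` so it can enter the
#' cutoff-detection stage.
#'
#' @param data Data frame with numeric `tb` (strictly increasing) and
#'   `mortality` (in \[0, 1\]) columns.
#' @param horizon Horizon in days the curve refers to.
#' @return A `tb_risk_curve`.
#' @export
as_risk_curve <- function(data, horizon = 90) {
  if (!all(c("tb", "mortality") %in% names(data))) {
    abort("`data` needs `tb` and `mortality` columns.",
          class = "bilicurve_config_error")
  }
  if (is.unsorted(data$tb, strictly = TRUE)) {
    abort("`tb` must be strictly increasing.", class = "bilicurve_config_error")
  }
  if (any(data$mortality < 0 | data$mortality > 1)) {
    abort("`mortality` must lie in [0, 1].", class = "bilicurve_config_error")
  }
  new_risk_curve(data$tb, data$mortality, horizon = horizon,
                 n_fit = NA_integer_, source = "external")
}
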