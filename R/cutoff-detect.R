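#' Acceleration (second derivative) of an adjusted mortality curve
#'
#' Refits a cubic smoothing spline to the (TB, mortality) curve and returns
#' its analytic second derivative — the "acceleration" of mortality with
#' respect to TB — on the curve's grid, with the outer 2.5% of the TB range
#' trimmed at each end where spline derivatives are unreliable. An internal
#' cross-check compares the analytic derivative with dense central finite
#' differences of the smoothed curve; the maximal discrepancy is stored in
#' the `fd_discrepancy` attribute (see [fd_second_derivative()]).
#'
#' @param curve A `tb_risk_curve` with at least 10 grid points.
#' @param trim Fraction of the TB range trimmed at each end (default 0.025).
#' @param df Optional smoothing-spline df (default: GCV).
#' @return A `tb_accel` tibble with columns `tb` and `acceleration`
#'   (probability per (mg/dL)^2), carrying the fitted spline and the
#'   finite-difference discrepancy as attributes.
#' @export
acceleration_curve <- function(curve, trim = 0.025, df = NULL) {
  ss <- curve_spline(curve, df = df)
  r <- range(curve$tb)
  lo <- r[1] + trim * diff(r)
  hi <- r[2] - trim * diff(r)
  keep <- curve$tb >= lo & curve$tb <= hi
  x <- curve$tb[keep]
  acc <- as.numeric(predict(ss, x = x, deriv = 2)$y)
  if (any(!is.finite(acc))) {
    abort("non-finite acceleration values.", class = "bilicurve_fit_error")
  }
  fd <- fd_second_derivative(ss, x)
  out <- tibble(tb = x, acceleration = acc)
  class(out) <- c("tb_accel", class(out))
  attr(out, "spline") <- ss
  attr(out, "fd_discrepancy") <- max(abs(acc - fd))
  attr(out, "horizon") <- attr(curve, "horizon")
  out
}

#' Central finite-difference second derivative of a fitted smoothing spline
#'
#' Independent check of the analytic spline derivative:
#' `(f(x+h) - 2 f(x) + f(x-h)) / h^2` evaluated on the smoothed curve.
#'
#' @param ss A `stats::smooth.spline` fit.
#' @param x Evaluation points.
#' @param h Step size (default 0.01 mg/dL).
#' @return Numeric vector.
#' @export
fd_second_derivative <- function(ss, x, h = 0.01) {
  f <- function(z) as.numeric(predict(ss, x = z)$y)
  (f(x + h) - 2 * f(x) + f(x - h)) / h^2
}

#' Locate the inflection points of the acceleration curve
#'
#' The mathematical cutoff is the TB at the maximum of the acceleration
#' curve (the peak); the saturation point is the TB at its minimum
#' restricted to values above the peak (the valley). Either is reported
#' absent (`NA`) when its absolute acceleration falls below
#' `min_amplitude`, which suppresses spurious inflections on near-linear
#' curves.
#'
#' @param acc A [acceleration_curve()] result.
#' @param min_amplitude Minimal |acceleration| for a real inflection
#'   (default 1e-5 per (mg/dL)^2).
#' @return A list with `peak` and `valley` (mg/dL, `NA` when absent).
#' @export
find_inflections <- function(acc, min_amplitude = 1e-5) {
  stopifnot(inherits(acc, "tb_accel"))
  if (nrow(acc) == 0) abort("empty acceleration curve.",
                            class = "bilicurve_config_error")
  i_peak <- which.max(acc$acceleration)
  peak <- if (abs(acc$acceleration[i_peak]) >= min_amplitude) {
    acc$tb[i_peak]
  } else {
    NA_real_
  }
  valley <- NA_real_
  if (!is.na(peak)) {
    above <- acc$tb > peak
    if (any(above)) {
      sub <- acc[above, ]
      i_val <- which.min(sub$acceleration)
      if (sub$acceleration[i_val] <= -min_amplitude) valley <- sub$tb[i_val]
    }
  }
  list(peak = peak, valley = valley)
}

#' Clinical TB cutoff: adjusted 28-day mortality reaching a target level
#'
#' Finds the smallest TB at which the smoothed adjusted 28-day mortality
#' curve crosses `level` (default 15%, the organ-failure mortality anchor)
#' from below. The bracketing grid interval is refined by root finding to
#' 1e-3 mg/dL. Returns `NA` when the curve never reaches the level.
#'
#' @param curve28 A 28-day `tb_risk_curve`.
#' @param level Target mortality probability in (0, 1); default 0.15.
#' @param df Optional smoothing-spline df passed to the curve smoother.
#' @return TB cutoff in mg/dL (`NA_real_` when absent), with the smoothed
#'   curve value at the cutoff in attribute `mortality_at_cutoff`.
#' @export
clinical_cutoff <- function(curve28, level = 0.15, df = NULL) {
  if (level <= 0 || level >= 1) {
    abort("`level` must lie in (0, 1).", class = "bilicurve_config_error")
  }
  h <- attr(curve28, "horizon")
  if (!is.null(h) && h != 28) {
    warn(sprintf("clinical cutoff is defined on the 28-day curve; got a %s-day curve.", h))
  }
  ss <- curve_spline(curve28, df = df)
  val <- as.numeric(predict(ss, x = curve28$tb)$y)
  below <- val < level
  cross <- which(!below & c(TRUE, below[-length(below)]))
  cross <- cross[cross > 1]
  if (!length(cross)) {
    out <- NA_real_
    attr(out, "mortality_at_cutoff") <- NA_real_
    return(out)
  }
  i <- cross[1]
  root <- uniroot(function(t) as.numeric(predict(ss, x = t)$y) - level,
                  lower = curve28$tb[i - 1], upper = curve28$tb[i],
                  tol = 1e-4)$root
  out <- round(root, 6)
  attr(out, "mortality_at_cutoff") <- as.numeric(predict(ss, x = out)$y)
  out
}

#' Exceedance and adjusted-mortality summary of TB cutoffs
#'
#' For each supplied cutoff, reports the fraction of the cohort with TB
#' strictly above it and the smoothed adjusted 28- and 90-day mortality.
#' The primary mortality figures are the curve values AT the cutoff (the
#' convention consistent with the clinical cutoff's definition); the mean
#' smoothed curve value among patients above the cutoff is emitted as a
#' secondary summary.
#'
#' @param cohort The analysis cohort the curves were fitted on.
#' @param curve28 The 28-day `tb_risk_curve` (or `NULL`).
#' @param curve90 The 90-day `tb_risk_curve` (or `NULL`).
#' @param cutoffs Named numeric vector or list of cutoffs (mg/dL), e.g.
#'   `c(mathematical = 14.2, valley = 24.8, clinical = 18.1)`; `NA` entries
#'   yield rows with absent fields.
#' @return A `tb_cutoffs` tibble: one row per cutoff with `cutoff`,
#'   `tb_cutoff`, `n_exceeding`, `frac_exceeding`, `mortality_28`,
#'   `mortality_90`, `mortality_28_above`, `mortality_90_above`.
#' @export
summarize_cutoffs <- function(cohort, curve28 = NULL, curve90 = NULL,
                              cutoffs) {
  cutoffs <- unlist(cutoffs)
  if (is.null(names(cutoffs)) || any(names(cutoffs) == "")) {
    abort("`cutoffs` must be named.", class = "bilicurve_config_error")
  }
  tb <- cohort$tb[!is.na(cohort$tb)]
  eval_curve <- function(curve, at) {
    if (is.null(curve) || is.na(at)) return(NA_real_)
    if (at > max(curve$tb) || at < min(curve$tb)) return(NA_real_)
    curve_value_at(curve, at)
  }
  mean_above <- function(curve, at) {
    if (is.null(curve) || is.na(at)) return(NA_real_)
    sel <- tb > at & tb <= max(curve$tb)
    if (!any(sel)) return(NA_real_)
    mean(curve_value_at(curve, tb[sel]))
  }
  rows <- purrr::imap(as.list(cutoffs), function(cut, nm) {
    n_exc <- if (is.na(cut)) NA_integer_ else sum(tb > cut)
    tibble(
      cutoff = nm,
      tb_cutoff = as.numeric(cut),
      n_exceeding = n_exc,
      frac_exceeding = if (is.na(cut)) NA_real_ else n_exc / length(tb),
      mortality_28 = eval_curve(curve28, cut),
      mortality_90 = eval_curve(curve90, cut),
      mortality_28_above = mean_above(curve28, cut),
      mortality_90_above = mean_above(curve90, cut)
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("tb_cutoffs", class(out))
  out
}
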