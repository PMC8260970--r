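#' Specify the true TB-to-log-hazard link of a synthetic cohort
#'
#' The link function `f(TB)` is the ground truth that the simulated cohort
#' carries on the log-hazard scale, and the quantity that the downstream
#' curve-fitting and cutoff-detection stages try to recover. Four shapes are
#' supported:
#'
#' * `"linear"`: `f(tb) = slope * tb` — a constant hazard ratio per mg/dL,
#'   the implicit model of a continuous Cox fit.
#' * `"sigmoid"`: `f(tb) = amplitude * plogis((tb - center) / scale)` — an
#'   S-shaped dose-response with an accelerating rise, a steep middle, and a
#'   saturation plateau, the pattern seen in cirrhosis cohorts.
#' * `"hinge"`: `f(tb) = log(1 + slope * pmax(tb - threshold, 0))` — no TB
#'   effect below the threshold; above it the cumulative hazard is
#'   multiplied by `1 + slope * (tb - threshold)`, so the mortality curve is
#'   flat below the threshold and rises essentially linearly above it — the
#'   pattern seen in advanced-fibrosis cohorts (no TB effect until roughly
#'   12 mg/dL, then a straight climb).
#' * `"flat"`: `f(tb) = level` — no TB effect at all; the null used to
#'   calibrate type-I error.
#'
#' @param shape One of `"linear"`, `"sigmoid"`, `"hinge"`, `"flat"`.
#' @param slope For `linear`, the log-hazard slope per mg/dL; for `hinge`,
#'   the per-mg/dL increase of the cumulative-hazard multiplier above the
#'   threshold.
#' @param amplitude Total log-hazard span of the sigmoid (must be >= 0).
#' @param center Sigmoid midpoint in mg/dL.
#' @param scale Sigmoid width in mg/dL (must be > 0).
#' @param threshold Hinge knot in mg/dL, inside (0, 50).
#' @param level Constant log-hazard offset for `flat`.
#'
#' @return An object of class `tb_link`.
#' @examples
#' lk <- tb_link("sigmoid", amplitude = 2.8, center = 15, scale = 3)
#' eval_link(lk, c(0, 15, 50))
#' @export
tb_link <- function(shape = c("linear", "sigmoid", "hinge", "flat"),
                    slope = 0.06, amplitude = 2.8, center = 15, scale = 3,
                    threshold = 12, level = 0) {
  shape <- match.arg(shape)
  if (scale <= 0) abort("`scale` must be > 0.", class = "bilicurve_config_error")
  if (amplitude < 0) abort("`amplitude` must be >= 0.", class = "bilicurve_config_error")
  if (threshold <= 0 || threshold >= 50) {
    abort("`threshold` must lie in (0, 50).", class = "bilicurve_config_error")
  }
  structure(
    list(shape = shape, slope = slope, amplitude = amplitude, center = center,
         scale = scale, threshold = threshold, level = level),
    class = "tb_link"
  )
}

#' Evaluate a TB link function
#'
#' @param link A [tb_link()] object.
#' @param tb Numeric vector of total bilirubin values (mg/dL).
#' @return Numeric vector of log-hazard contributions.
#' @export
eval_link <- function(link, tb) {
  stopifnot(inherits(link, "tb_link"))
  switch(link$shape,
    linear  = link$slope * tb,
    sigmoid = link$amplitude * plogis((tb - link$center) / link$scale),
    hinge   = log1p(link$slope * pmax(tb - link$threshold, 0)),
    flat    = rep(link$level, length(tb))
  )
}

#' @export
print.tb_link <- function(x, ...) {
  pars <- switch(x$shape,
    linear  = sprintf("slope = %g per mg/dL", x$slope),
    sigmoid = sprintf("amplitude = %g, center = %g mg/dL, scale = %g mg/dL",
                      x$amplitude, x$center, x$scale),
    hinge   = sprintf("threshold = %g mg/dL, slope = %g per mg/dL",
                      x$threshold, x$slope),
    flat    = sprintf("level = %g", x$level)
  )
  cat(sprintf("<tb_link: %s (%s)>\n", x$shape, pars))
  invisible(x)
}
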