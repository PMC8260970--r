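#' Plot an adjusted TB-mortality correlation curve
#'
#' @param object A `tb_risk_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.tb_risk_curve <- function(object, ...) {
  h <- attr(object, "horizon") %||% NA
  ggplot2::ggplot(object, ggplot2::aes(x = .data$tb, y = .data$mortality)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(
      x = "Total bilirubin (mg/dL)",
      y = sprintf("Adjusted %s-day transplantation-free mortality", h),
      title = "TB-mortality correlation curve"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an acceleration curve with its inflection points
#'
#' @param object A `tb_accel`.
#' @param min_amplitude Passed to [find_inflections()] for the annotated
#'   peak/valley.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.tb_accel <- function(object, min_amplitude = 1e-5, ...) {
  infl <- find_inflections(object, min_amplitude = min_amplitude)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$tb, y = .data$acceleration)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(linewidth = 0.8, colour = "#b2182b") +
    ggplot2::labs(
      x = "Total bilirubin (mg/dL)",
      y = expression("Acceleration (probability per (mg/dL)"^2 * ")"),
      title = "Second derivative of the TB-mortality curve"
    ) +
    ggplot2::theme_minimal()
  marks <- c(peak = infl$peak, valley = infl$valley)
  marks <- marks[!is.na(marks)]
  if (length(marks)) {
    p <- p + ggplot2::geom_vline(xintercept = unname(marks),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Forest-style plot of binned TB hazard ratios
#'
#' @param object A `tb_cox` fitted with `exposure = "categorical"`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.tb_cox <- function(object, ...) {
  tab <- filter(object$table, grepl("^tb", .data$term))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$term, y = .data$hr)) +
    ggplot2::geom_hline(yintercept = 1, colour = "grey70") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "Hazard ratio (95% CI, log scale)",
                  title = "Hazard of 90-day mortality by TB") +
    ggplot2::theme_minimal()
}
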