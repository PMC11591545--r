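# ggplot2 front-ends for the main result types.

#' Plot a PTA curve
#'
#' PTA versus MIC on a log2 axis with the 90% desirability bound.
#'
#' @param object a [pta_curve()] result (several can be row-bound first to
#'   overlay regimens or binding scenarios)
#' @param ... unused
#' @return a ggplot
#' @method autoplot pta_result
#' @export
autoplot.pta_result <- function(object, ...) {
  grp <- interaction(object$regimen, object$pb, drop = TRUE)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mic, y = .data$pta,
                                       colour = .data$regimen,
                                       linetype = factor(.data$pb),
                                       group = grp)) +
    ggplot2::geom_hline(yintercept = 90, linetype = "dotted", colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_x_continuous(trans = "log2",
                                breaks = unique(object$mic),
                                labels = unique(object$mic)) +
    ggplot2::labs(x = "MIC (mg/L)", y = "PTA (%)",
                  colour = "Regimen", linetype = "Protein binding (%)") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}

#' Plot a visual predictive check
#'
#' Prediction ribbons per simulated percentile with the observed
#' percentiles overlaid.
#'
#' @param object a [vpc()] result
#' @param ... unused
#' @return a ggplot
#' @method autoplot vpc_result
#' @export
autoplot.vpc_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_time,
                                       group = .data$percentile)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$band_lower,
                                      ymax = .data$band_upper,
                                      fill = factor(.data$percentile)),
                         alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed,
                                    colour = factor(.data$percentile))) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed,
                                     colour = factor(.data$percentile))) +
    ggplot2::labs(x = "Time (h)", y = "Concentration (mg/L)",
                  colour = "Observed percentile", fill = "Prediction band") +
    ggplot2::theme_minimal()
}

#' Goodness-of-fit plot for a population fit
#'
#' Observed versus population and individual predictions with the identity
#' line.
#'
#' @param object a [fit_popmodel()] result
#' @param ... unused
#' @return a ggplot
#' @method autoplot pk_fit
#' @export
autoplot.pk_fit <- function(object, ...) {
  g <- gof(object)
  long <- tidyr::pivot_longer(g$table, c("ppred", "ipred"),
                              names_to = "type", values_to = "pred")
  long$type <- ifelse(long$type == "ppred",
                      sprintf("population (R² = %.3f)", g$r2_population),
                      sprintf("individual (R² = %.3f)", g$r2_individual))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pred, y = .data$obs)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~type, scales = "free") +
    ggplot2::labs(x = "Predicted concentration (mg/L)",
                  y = "Observed concentration (mg/L)") +
    ggplot2::theme_minimal()
}

#' Plot simulated concentration percentile bands
#'
#' @param bands a [profile_bands()] tibble (columns `time`, `p5`, `p50`,
#'   `p95` by default)
#' @param lower,upper,mid column names of the band bounds and centre line
#' @return a ggplot
#' @export
plot_profile_bands <- function(bands, lower = "p5", upper = "p95", mid = "p50") {
  ggplot2::ggplot(bands, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[[lower]],
                                      ymax = .data[[upper]]),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data[[mid]]), colour = "steelblue4") +
    ggplot2::labs(x = "Time (h)", y = "Concentration (mg/L)") +
    ggplot2::theme_minimal()
}
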