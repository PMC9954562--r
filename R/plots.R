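#' Plot a growth fit
#'
#' Counts on a log axis with the fitted exponential and the selected fit
#' window shaded.
#'
#' @param object a `growth_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot growth_fit
#' @export
autoplot.growth_fit <- function(object, ...) {
  dat <- object$data
  grid <- tibble(
    time_d = seq(min(dat$time_d), max(dat$time_d), length.out = 100))
  grid$cells <- object$n0 *
    exp((grid$time_d - object$window[1]) / object$tau)
  ggplot2::ggplot(dat, ggplot2::aes(.data$time_d, .data$cells)) +
    ggplot2::annotate("rect", xmin = object$window[1],
                      xmax = object$window[2], ymin = -Inf, ymax = Inf,
                      alpha = 0.08) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (days)", y = "cells per biosphere",
                  title = sprintf("tau = %.3g d, doubling %.3g d",
                                  object$tau, object$doubling_time)) +
    ggplot2::theme_minimal()
}

#' Plot observed versus predicted spheroid areas
#'
#' Observed per-time median and interquartile range of spheroid area against
#' the spherical-growth prediction anchored at the first time point.
#'
#' @param object a `compactness_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot compactness_report
#' @export
autoplot.compactness_report <- function(object, ...) {
  tb <- object$table
  grid <- tibble(
    time_d = seq(min(tb$time_d), max(tb$time_d), length.out = 100))
  grid$area_pred <- predict_area(object$prediction, grid$time_d)
  ggplot2::ggplot(tb, ggplot2::aes(.data$time_d, .data$area_median)) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$area_pred),
                       colour = "firebrick", linetype = 2) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$area_q1,
                                          ymax = .data$area_q3)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (days)", y = expression(area ~ (mu * m^2)),
                  title = sprintf("verdict: %s", object$verdict)) +
    ggplot2::theme_minimal()
}

#' Plot circularity spread by size stratum
#'
#' Boxplots of circularity for the small and large halves of the
#' median-area split, annotated with the Levene p-value.
#'
#' @param object a `circ_var_test`.
#' @param measures the measurement table the test was built from.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot circ_var_test
#' @export
autoplot.circ_var_test <- function(object, measures, ...) {
  dat <- tibble(group = object$split$assignment$group,
                circularity = measures$circularity[
                  is.finite(measures$area_um2) &
                    is.finite(measures$circularity)])
  ggplot2::ggplot(dat, ggplot2::aes(.data$group, .data$circularity)) +
    ggplot2::geom_boxplot(width = 0.5) +
    ggplot2::labs(x = NULL, y = "circularity",
                  title = sprintf("Levene (%s) p = %.3g",
                                  object$test$variant,
                                  object$test$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot cohort sphericity by volume group
#'
#' @param object a `run_report` from [run_cohort_analysis()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot run_report
#' @export
autoplot.run_report <- function(object, ...) {
  if (object$kind != "cohort")
    abort("autoplot is defined for cohort run reports.")
  ggplot2::ggplot(object$cohort,
                  ggplot2::aes(.data$size_group, .data$sphericity)) +
    ggplot2::geom_boxplot(width = 0.5) +
    ggplot2::labs(x = sprintf("volume group (threshold %.3g cm^3)",
                              object$split$threshold),
                  y = "sphericity",
                  title = sprintf("Mann-Whitney p = %.3g",
                                  object$rank_test$p_value)) +
    ggplot2::theme_minimal()
}
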