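#' Fit the exponential proliferation model to a count series
#'
#' Ordinary least squares of `log(cells)` on time inside the fit window,
#' matching a constant-coefficient-of-variation noise model. The e-folding
#' time is `tau = 1/slope`; `n0` is the back-transformed intercept at the
#' window start; the doubling time is `tau * log(2)`.
#'
#' @param data a data frame of counts over time (e.g. from
#'   [generate_count_series()]).
#' @param time,count column names (tidy-eval) holding days and cell counts.
#' @param window optional `c(t_start, t_end)` restricting the fit; `NULL`
#'   uses all points, `"auto"` runs [select_exponential_window()] first.
#' @param min_points minimum window size when `window = "auto"`.
#' @return An object of class `growth_fit` with fields `n0`, `tau`,
#'   `doubling_time`, `window`, `r_squared`, `n_points`, and the fitted data.
#' @export
fit_exponential <- function(data, time = time_d, count = cells,
                            window = NULL, min_points = 4L) {
  tv <- eval_tidy(enquo(time), data)
  cv <- eval_tidy(enquo(count), data)
  if (any(cv < 1)) abort("counts must be >= 1.")
  if (identical(window, "auto")) {
    window <- select_exponential_window(data, {{ time }}, {{ count }},
                                        min_points = min_points)
  }
  if (!is.null(window)) {
    keep <- tv >= window[1] & tv <= window[2]
    tv <- tv[keep]; cv <- cv[keep]
  }
  if (length(tv) < 3L)
    abort("need at least 3 points inside the fit window.")
  ord <- order(tv)
  tv <- tv[ord]; cv <- cv[ord]
  fit <- lm(log(cv) ~ tv)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    abort("no exponential growth in window (slope <= 0).")
  tau <- 1 / slope
  t_start <- tv[1]
  n0 <- exp(unname(coef(fit)[1]) + slope * t_start)
  r2 <- stats::cor(tv, log(cv))^2  # = R^2 for simple OLS
  structure(
    list(n0 = n0, tau = tau, doubling_time = tau * log(2),
         window = c(t_start, tv[length(tv)]), r_squared = r2,
         n_points = length(tv),
         data = tibble(time_d = tv, cells = cv)),
    class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "<growth_fit> tau = %.4g d (doubling %.4g d), n0 = %.4g cells\n  window [%g, %g] d, %d points, R^2 = %.4f\n",
    x$tau, x$doubling_time, x$n0, x$window[1], x$window[2], x$n_points,
    x$r_squared))
  invisible(x)
}

#' Select the exponential-growth window of a count series
#'
#' Scans every contiguous sub-series of at least `min_points` points and
#' returns the one maximizing the log-linear R^2; ties (to 1e-10) are broken
#' toward the wider, then earlier window. A purely exponential series
#' therefore yields the full range, while a series with a saturating tail
#' excludes the plateau.
#'
#' @inheritParams fit_exponential
#' @param min_points minimum number of points in the window.
#' @return `c(t_start, t_end)` in days.
#' @export
select_exponential_window <- function(data, time = time_d, count = cells,
                                      min_points = 4L) {
  tv <- eval_tidy(enquo(time), data)
  cv <- eval_tidy(enquo(count), data)
  ord <- order(tv)
  tv <- tv[ord]; cv <- cv[ord]
  n <- length(tv)
  if (n < min_points)
    abort(sprintf("series has %d points; need >= %d.", n, min_points))
  lc <- log(cv)
  best <- NULL
  for (i in seq_len(n - min_points + 1L)) {
    for (j in seq(i + min_points - 1L, n)) {
      ss <- i:j
      # flat (zero-variance) segments score 0 rather than warn
      f <- if (stats::sd(lc[ss]) == 0) 0 else stats::cor(tv[ss], lc[ss])^2
      if (!is.finite(f)) f <- 0
      cand <- c(score = round(f, 10), width = j - i + 1L, start = -i)
      if (is.null(best) ||
          cand["score"] > best["score"] ||
          (cand["score"] == best["score"] && cand["width"] > best["width"]) ||
          (cand["score"] == best["score"] && cand["width"] == best["width"] &&
             cand["start"] > best["start"])) {
        best <- cand
        bw <- c(tv[i], tv[j])
      }
    }
  }
  bw
}

#' Spherical-growth prediction parameters
#'
#' Holds the initial diameter/area and the proliferation time that define
#' the spherical growth laws `d(t) = d0 exp((t - t0)/(3 tau))` and
#' `A(t) = A0 exp(2 (t - t0)/(3 tau))`. If only one of `d0`/`A0` is given
#' the other is derived from the disk relation `A0 = pi d0^2 / 4`, keeping
#' the pair mutually consistent.
#'
#' @param tau e-folding time of the cell count, days.
#' @param d0 initial equivalent diameter, um.
#' @param A0 initial area, um^2.
#' @param t0 reference time, days.
#' @param cell_volume characteristic single-cell volume in um^3
#'   (informational).
#' @return An object of class `spherical_prediction`.
#' @export
spherical_prediction <- function(tau, d0 = NULL, A0 = NULL, t0 = 0,
                                 cell_volume = NA_real_) {
  if (tau <= 0) abort("`tau` must be > 0.")
  if (is.null(d0) && is.null(A0)) abort("give `d0` or `A0`.")
  if (is.null(A0)) A0 <- pi * d0^2 / 4
  if (is.null(d0)) d0 <- 2 * sqrt(A0 / pi)
  if (abs(A0 - pi * d0^2 / 4) > 1e-6 * A0)
    abort("`d0` and `A0` are inconsistent: A0 must equal pi d0^2 / 4.")
  if (d0 <= 0) abort("`d0` must be > 0.")
  structure(list(d0 = d0, A0 = A0, tau = tau, t0 = t0,
                 cell_volume = cell_volume),
            class = "spherical_prediction")
}

#' Predicted diameter under spherical growth
#'
#' @param pred a [spherical_prediction].
#' @param t evaluation times in days (all `>= t0`).
#' @return Diameters in um.
#' @export
predict_diameter <- function(pred, t) {
  if (any(t < pred$t0)) abort("`t` must be >= t0.")
  pred$d0 * exp((t - pred$t0) / (3 * pred$tau))
}

#' Predicted area under spherical growth
#'
#' @inheritParams predict_diameter
#' @return Areas in um^2.
#' @export
predict_area <- function(pred, t) {
  if (any(t < pred$t0)) abort("`t` must be >= t0.")
  pred$A0 * exp(2 * (t - pred$t0) / (3 * pred$tau))
}

#' Compactness of observed spheroid sizes against the spherical prediction
#'
#' Anchors the prediction at the median area of the earliest time point,
#' propagates it with the count-derived `tau`, and forms the compactness
#' index `kappa(t) = observed median area / predicted area` per time point.
#' The verdict is `"compact"` iff every `kappa(t)` lies within
#' `[1/kappa_star, kappa_star]`.
#'
#' @param measures shape-measurement table (needs `time_d` and `area_um2`
#'   columns, e.g. from [measure_shapes()]).
#' @param fit a [fit_exponential()] result from the same culture, or a bare
#'   `tau` in days.
#' @param kappa_star tolerance factor (> 1) for the verdict band.
#' @param min_objects minimum objects required per time point.
#' @return An object of class `compactness_report`: `$table` (per time:
#'   `time_d`, `n_obs`, `area_median`, `area_q1`, `area_q3`, `area_pred`,
#'   `kappa`), `$verdict`, `$kappa_star`, `$tau`.
#' @export
compactness_report <- function(measures, fit, kappa_star = 1.5,
                               min_objects = 10L) {
  if (kappa_star <= 1) abort("`kappa_star` must be > 1.")
  tau <- if (inherits(fit, "growth_fit")) fit$tau else as.numeric(fit)
  if (!all(c("time_d", "area_um2") %in% names(measures)))
    abort("`measures` needs `time_d` and `area_um2` columns.")
  bytime <- measures |>
    dplyr::filter(is.finite(.data$area_um2), is.finite(.data$time_d)) |>
    dplyr::summarise(
      n_obs = dplyr::n(),
      area_median = median(.data$area_um2),
      area_q1 = quantile(.data$area_um2, 0.25, names = FALSE),
      area_q3 = quantile(.data$area_um2, 0.75, names = FALSE),
      .by = "time_d") |>
    dplyr::arrange(.data$time_d)
  if (nrow(bytime) < 2L)
    abort("need measurements at >= 2 time points.")
  if (any(bytime$n_obs < min_objects))
    abort(sprintf("every time point needs >= %d objects.", min_objects))
  pred <- spherical_prediction(tau, A0 = bytime$area_median[1],
                               t0 = bytime$time_d[1])
  bytime$area_pred <- predict_area(pred, bytime$time_d)
  bytime$kappa <- bytime$area_median / bytime$area_pred
  inside <- bytime$kappa >= 1 / kappa_star & bytime$kappa <= kappa_star
  structure(
    list(table = bytime,
         verdict = if (all(inside)) "compact" else "non-compact",
         kappa_star = kappa_star, tau = tau, prediction = pred),
    class = "compactness_report")
}

#' @export
print.compactness_report <- function(x, ...) {
  cat(sprintf("<compactness_report> verdict: %s (kappa* = %.3g, tau = %.3g d)\n",
              x$verdict, x$kappa_star, x$tau))
  print(x$table)
  invisible(x)
}
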