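#' Tidy a growth fit
#'
#' @param x a `growth_fit`.
#' @param ... unused.
#' @return A tibble with one row per parameter (`n0`, `tau`,
#'   `doubling_time`).
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(term = c("n0", "tau", "doubling_time"),
         estimate = c(x$n0, x$tau, x$doubling_time),
         unit = c("cells", "days", "days"))
}

#' One-row summary of a growth fit
#'
#' @inheritParams tidy.growth_fit
#' @return A one-row tibble: `n0`, `tau`, `doubling_time`, `r_squared`,
#'   `n_points`, `window_start`, `window_end`.
#' @export
glance.growth_fit <- function(x, ...) {
  tibble(n0 = x$n0, tau = x$tau, doubling_time = x$doubling_time,
         r_squared = x$r_squared, n_points = x$n_points,
         window_start = x$window[1], window_end = x$window[2])
}

#' Tidy a Levene variance test
#'
#' @param x a `levene_test`.
#' @param ... unused.
#' @return One-row tibble: `statistic`, `df1`, `df2`, `p_value`, `variant`.
#' @export
tidy.levene_test <- function(x, ...) {
  tibble(statistic = x$statistic, df1 = unname(x$df[1]),
         df2 = unname(x$df[2]), p_value = x$p_value, variant = x$variant)
}

#' Tidy a Mann-Whitney rank test
#'
#' @param x a `rank_test`.
#' @param ... unused.
#' @return One-row tibble: `statistic`, `p_value`, `method`, `n1`, `n2`,
#'   `median1`, `median2`.
#' @export
tidy.rank_test <- function(x, ...) {
  tibble(statistic = x$U, p_value = x$p_value, method = x$method,
         n1 = unname(x$group_sizes[1]), n2 = unname(x$group_sizes[2]),
         median1 = unname(x$medians[1]), median2 = unname(x$medians[2]))
}

#' Tidy a compactness report
#'
#' @param x a `compactness_report`.
#' @param ... unused.
#' @return The per-time table with the verdict attached as a column.
#' @export
tidy.compactness_report <- function(x, ...) {
  dplyr::mutate(x$table, verdict = x$verdict, kappa_star = x$kappa_star)
}

#' Tidy a circularity-variance test
#'
#' @param x a `circ_var_test`.
#' @param ... unused.
#' @return One-row tibble combining the split threshold and the Levene
#'   result.
#' @export
tidy.circ_var_test <- function(x, ...) {
  dplyr::mutate(tidy(x$test),
                split_variable = x$split$variable,
                threshold = x$split$threshold,
                n_small = length(x$split$small_ids),
                n_large = length(x$split$large_ids),
                .before = 1)
}
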