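#' Levene-family test for equality of variances
#'
#' The quadratic variant (default) transforms each observation to its
#' squared deviation from the group mean, `z_ij = (x_ij - xbar_i)^2`, and
#' assesses the one-way ANOVA F statistic on the `z_ij` against
#' `F(k - 1, N - k)`. The classical absolute-deviation variant
#' (`"absolute"`) and the median-centred Brown-Forsythe variant
#' (`"median"`) are available behind the `variant` flag.
#'
#' @param x a list of numeric vectors (one per group), or a data frame.
#' @param ... passed between methods.
#' @return An object of class `levene_test`: `statistic` (W), `df`, `p_value`,
#'   `variant`, `group_sizes`, `group_variances`, `group_labels`.
#' @export
levene_quadratic <- function(x, ...) UseMethod("levene_quadratic")

#' @rdname levene_quadratic
#' @param variant `"quadratic"` (squared deviations from the mean),
#'   `"absolute"` (absolute deviations from the mean) or `"median"`
#'   (absolute deviations from the median).
#' @export
levene_quadratic.default <- function(x, variant = c("quadratic", "absolute",
                                                    "median"), ...) {
  variant <- match.arg(variant)
  if (!is.list(x)) abort("`x` must be a list of numeric group samples.")
  groups <- lapply(x, function(g) as.numeric(g[is.finite(g)]))
  k <- length(groups)
  if (k < 2L) abort("need at least 2 groups.")
  sizes <- lengths(groups)
  if (any(sizes < 2L)) abort("every group needs at least 2 observations.")
  z <- lapply(groups, function(g) {
    switch(variant,
           quadratic = (g - mean(g))^2,
           absolute = abs(g - mean(g)),
           median = abs(g - median(g)))
  })
  N <- sum(sizes)
  zall <- unlist(z)
  zbar <- mean(zall)
  zmeans <- vapply(z, mean, numeric(1))
  ssb <- sum(sizes * (zmeans - zbar)^2)
  ssw <- sum(vapply(seq_len(k), function(i) sum((z[[i]] - zmeans[i])^2),
                    numeric(1)))
  df1 <- k - 1L
  df2 <- N - k
  if (ssb == 0) {
    W <- 0; p <- 1
  } else if (ssw == 0) {
    W <- Inf; p <- 0
  } else {
    W <- (ssb / df1) / (ssw / df2)
    p <- pf(W, df1, df2, lower.tail = FALSE)
  }
  labs <- names(groups) %||% as.character(seq_len(k))
  structure(
    list(statistic = W, df = c(df1 = df1, df2 = df2), p_value = p,
         variant = variant, group_sizes = setNames(sizes, labs),
         group_variances = setNames(vapply(groups, var, numeric(1)), labs),
         group_labels = labs),
    class = "levene_test")
}

#' @rdname levene_quadratic
#' @param value,group column names (tidy-eval) for the data-frame method.
#' @export
levene_quadratic.data.frame <- function(x, value, group,
                                        variant = c("quadratic", "absolute",
                                                    "median"), ...) {
  v <- eval_tidy(enquo(value), x)
  g <- eval_tidy(enquo(group), x)
  levene_quadratic(split(v, g), variant = match.arg(variant))
}

#' @export
print.levene_test <- function(x, ...) {
  cat(sprintf("<levene_test> variant %s: W = %.4g on (%d, %d) df, p = %.4g\n",
              x$variant, x$statistic, x$df[1], x$df[2], x$p_value))
  cat("  group sizes:", paste(x$group_sizes, collapse = ", "),
      "  variances:", paste(signif(x$group_variances, 4), collapse = ", "),
      "\n")
  invisible(x)
}

# Exact null distribution of the Mann-Whitney U statistic (no ties):
# counts[u + 1] = number of the C(n1+n2, n1) rank splits with U = u.
# Generating function is the Gaussian binomial coefficient
# prod_{i=1}^{n1} (1 - x^(n2+i)) / (1 - x^i), evaluated mod x^(n1 n2 + 1)
# (multiplication and series division commute with truncation).
mw_exact_counts <- function(n1, n2) {
  L <- n1 * n2 + 1L
  cnt <- numeric(L)
  cnt[1] <- 1
  for (i in seq_len(n1)) {
    s <- n2 + i
    if (s < L) cnt[(s + 1L):L] <- cnt[(s + 1L):L] - cnt[1:(L - s)]
    if (i < L) for (u in (i + 1L):L) cnt[u] <- cnt[u] + cnt[u - i]
  }
  cnt
}

#' Mann-Whitney rank-sum test
#'
#' Computes the U statistic from rank sums with midranks for ties. The
#' `"exact"` method evaluates the exact permutation null of U (available
#' only without ties); `"normal"` uses the normal approximation with
#' continuity and tie corrections; `"auto"` (default) picks the exact
#' method when `n1 + n2 <= 20` and there are no ties.
#'
#' @param x numeric sample, list of two samples, or a data frame.
#' @param ... passed between methods.
#' @return An object of class `rank_test`: `U` (for the first sample),
#'   `p_value` (two-sided), `method`, `group_sizes`, `medians`,
#'   `tie_correction_applied`.
#' @export
mann_whitney <- function(x, ...) UseMethod("mann_whitney")

#' @rdname mann_whitney
#' @param y second numeric sample.
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @export
mann_whitney.default <- function(x, y, method = c("auto", "exact", "normal"),
                                 alternative = c("two.sided", "less",
                                                 "greater"), ...) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  a <- as.numeric(x[is.finite(x)])
  b <- as.numeric(y[is.finite(y)])
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0L || n2 == 0L) abort("both samples must be non-empty.")
  comb <- c(a, b)
  rk <- rank(comb)  # midranks
  ties <- anyDuplicated(comb) > 0L
  U1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  if (method == "auto") method <- if (!ties && n1 + n2 <= 20L) "exact" else "normal"
  if (method == "exact" && ties) {
    warn("ties present: falling back to the normal approximation")
    method <- "normal"
  }
  if (method == "exact") {
    cnt <- mw_exact_counts(n1, n2)
    tot <- sum(cnt)
    ple <- cumsum(cnt)[U1 + 1L] / tot
    pge <- rev(cumsum(rev(cnt)))[U1 + 1L] / tot
    p <- switch(alternative,
                two.sided = min(1, 2 * min(ple, pge)),
                less = ple, greater = pge)
  } else {
    N <- n1 + n2
    tt <- table(comb)
    tiecor <- sum(tt^3 - tt) / (N * (N - 1))
    sig2 <- n1 * n2 / 12 * (N + 1 - tiecor)
    mu <- n1 * n2 / 2
    dev <- U1 - mu
    corr <- switch(alternative,  # continuity correction toward the mean
                   two.sided = sign(dev) * 0.5,
                   greater = 0.5, less = -0.5)
    z <- (dev - corr) / sqrt(sig2)
    p <- switch(alternative,
                two.sided = min(1, 2 * pnorm(-abs(z))),
                less = pnorm(z),
                greater = pnorm(z, lower.tail = FALSE))
  }
  structure(
    list(U = U1, U_other = U2, p_value = p, method = method,
         alternative = alternative,
         group_sizes = c(n1 = n1, n2 = n2),
         medians = c(median(a), median(b)),
         tie_correction_applied = ties && method == "normal"),
    class = "rank_test")
}

#' @rdname mann_whitney
#' @param value,group column names (tidy-eval); `group` must take exactly
#'   two levels.
#' @export
mann_whitney.data.frame <- function(x, value, group,
                                    method = c("auto", "exact", "normal"),
                                    alternative = c("two.sided", "less",
                                                    "greater"), ...) {
  v <- eval_tidy(enquo(value), x)
  g <- eval_tidy(enquo(group), x)
  sp <- split(v, g)
  if (length(sp) != 2L) abort("`group` must have exactly two levels.")
  out <- mann_whitney(sp[[1]], sp[[2]], method = match.arg(method),
                      alternative = match.arg(alternative))
  names(out$group_sizes) <- names(sp)
  names(out$medians) <- names(sp)
  out
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("<rank_test> Mann-Whitney U = %g (%s), two groups n = %s, p = %.4g\n",
              x$U, x$method, paste(x$group_sizes, collapse = "/"), x$p_value))
  cat("  medians:", paste(signif(x$medians, 4), collapse = " vs "), "\n")
  invisible(x)
}

#' Median split of a measurement table
#'
#' Splits rows into `"small"` (value <= sample median) and `"large"`
#' (value > median) groups. Median-valued rows go to `"small"`, making the
#' rule deterministic under ties.
#'
#' @param data a data frame with at least 2 rows.
#' @param variable column (tidy-eval) to split on.
#' @param id optional column holding object ids; row numbers otherwise.
#' @return An object of class `size_split`: `threshold`, `variable`,
#'   `small_ids`, `large_ids`, and `assignment` (tibble `id`, `value`,
#'   `group`).
#' @export
stratify_by_median <- function(data, variable, id = NULL) {
  v <- eval_tidy(enquo(variable), data)
  if (!is.numeric(v)) abort("`variable` must be numeric.")
  if (length(v) < 2L) abort("need at least 2 rows.")
  ids <- if (rlang::quo_is_null(enquo(id))) as.character(seq_along(v))
  else as.character(eval_tidy(enquo(id), data))
  thr <- median(v)
  grp <- ifelse(v <= thr, "small", "large")
  if (!any(grp == "large"))
    abort("constant variable: the large group is empty.")
  structure(
    list(threshold = thr, variable = as_name(enquo(variable)),
         small_ids = ids[grp == "small"], large_ids = ids[grp == "large"],
         assignment = tibble(id = ids, value = v,
                             group = factor(grp, c("small", "large")))),
    class = "size_split")
}

#' @export
print.size_split <- function(x, ...) {
  cat(sprintf("<size_split> %s at median %.4g: %d small / %d large\n",
              x$variable, x$threshold, length(x$small_ids),
              length(x$large_ids)))
  invisible(x)
}

#' Circularity-variance test across size strata
#'
#' Splits a shape-measurement table at the median area and runs the Levene
#' quadratic test on the circularity of the small versus large group — the
#' per-culture surface-regularity comparison.
#'
#' @param measures measurement table with `area_um2` and `circularity`
#'   columns (e.g. from [measure_shapes()]).
#' @param variant Levene variant, see [levene_quadratic()].
#' @return An object of class `circ_var_test`: `$test` ([levene_quadratic()]
#'   result), `$split` ([stratify_by_median()] result).
#' @export
circularity_variance_test <- function(measures,
                                      variant = c("quadratic", "absolute",
                                                  "median")) {
  variant <- match.arg(variant)
  if (!all(c("area_um2", "circularity") %in% names(measures)))
    abort("`measures` needs `area_um2` and `circularity` columns.")
  ok <- is.finite(measures$area_um2) & is.finite(measures$circularity)
  measures <- measures[ok, , drop = FALSE]
  if (nrow(measures) < 4L)
    abort("need at least 4 objects with valid circularity.")
  strat <- stratify_by_median(measures, area_um2)
  groups <- split(measures$circularity, strat$assignment$group)
  test <- levene_quadratic(groups, variant = variant)
  structure(list(test = test, split = strat), class = "circ_var_test")
}

#' @export
print.circ_var_test <- function(x, ...) {
  print(x$split); print(x$test)
  invisible(x)
}
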