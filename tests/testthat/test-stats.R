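test_that("Levene quadratic statistic behaves on canonical examples", {
  eq <- levene_quadratic(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_equal(unname(eq$df), c(1, 4))

  ue <- levene_quadratic(list(c(0, 0, 0, 0), c(-5, 0, 5, 10)))
  expect_gt(ue$statistic, 0)
  expect_lt(ue$p_value, 1)

  expect_error(levene_quadratic(list(1, c(1, 2))), "at least 2 observations")
  expect_error(levene_quadratic(list(c(1, 2))), "2 groups")
  const <- levene_quadratic(list(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(const$statistic, 0)
  expect_equal(const$p_value, 1)
})

test_that("absolute and median Levene variants match car::leveneTest", {
  skip_if_not_installed("car")
  set.seed(14)
  x <- rnorm(60)
  g <- rep(c("a", "b", "c"), each = 20)
  x[g == "b"] <- 2 * x[g == "b"]
  oa <- levene_quadratic(split(x, g), variant = "absolute")
  ca <- car::leveneTest(x, factor(g), center = mean)
  expect_equal(oa$statistic, ca$`F value`[1], tolerance = 1e-10)
  expect_equal(oa$p_value, ca$`Pr(>F)`[1], tolerance = 1e-10)
  om <- levene_quadratic(split(x, g), variant = "median")
  cm <- car::leveneTest(x, factor(g), center = median)
  expect_equal(om$statistic, cm$`F value`[1], tolerance = 1e-10)
})

test_that("quadratic Levene F p-value agrees with its permutation null", {
  set.seed(31)
  for (rep in 1:6) {
    x <- c(rnorm(60), rnorm(60, sd = sqrt(2)))
    g <- rep(1:2, each = 60)
    obs <- levene_quadratic(split(x, g))
    B <- 1200
    perm <- vapply(seq_len(B), function(b) {
      gs <- sample(g)
      levene_quadratic(split(x, gs))$statistic
    }, numeric(1))
    p_perm <- (1 + sum(perm >= obs$statistic)) / (B + 1)
    se <- sqrt(p_perm * (1 - p_perm) / B)
    expect_lt(abs(obs$p_value - p_perm), 4 * se + 0.01)
  }
})

test_that("Levene is invariant under adding a constant", {
  x <- list(rnorm(20), rnorm(20, sd = 2))
  a <- levene_quadratic(x)
  b <- levene_quadratic(lapply(x, function(v) v + 100))
  expect_equal(a$statistic, b$statistic, tolerance = 1e-9)
})

test_that("Mann-Whitney exact p matches enumeration on the textbook case", {
  mt <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mt$U, 0)
  expect_equal(mt$method, "exact")
  expect_equal(mt$p_value, 1 / 3, tolerance = 1e-12)
  same <- mann_whitney(c(5, 6, 7), c(5, 6, 7))
  expect_gte(same$p_value, 0.99)
})

test_that("exact Mann-Whitney equals brute-force enumeration for all small splits", {
  set.seed(8)
  for (n1 in 1:6) {
    for (n2 in n1:(8 - n1)) {
      if (n2 < 1) next
      vals <- sample(100, n1 + n2)  # distinct -> no ties
      a <- vals[seq_len(n1)]; b <- vals[-seq_len(n1)]
      p_pkg <- mann_whitney(a, b, method = "exact")$p_value
      expect_equal(p_pkg, mw_brute_force(a, b), tolerance = 1e-12,
                   info = sprintf("n1=%d n2=%d", n1, n2))
    }
  }
})

test_that("Mann-Whitney handles ties via the corrected normal approximation", {
  a <- c(1, 2, 2, 3, 5, 6); b <- c(2, 3, 3, 4, 7, 8, 8)
  expect_warning(mt <- mann_whitney(a, b, method = "exact"), "ties")
  expect_equal(mt$method, "normal")
  expect_true(mt$tie_correction_applied)
  wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(mt$p_value, wt$p.value, tolerance = 1e-10)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("rank test is invariant under monotone transforms and shifts", {
  set.seed(4)
  a <- rlnorm(12); b <- rlnorm(15, meanlog = 0.8)
  p0 <- mann_whitney(a, b)$p_value
  expect_equal(mann_whitney(log(a), log(b))$p_value, p0, tolerance = 1e-12)
  expect_equal(mann_whitney(a + 7, b + 7)$p_value, p0, tolerance = 1e-12)
  expect_equal(mann_whitney(sqrt(a), sqrt(b))$p_value, p0, tolerance = 1e-12)
})

test_that("median stratification follows the documented tie rule", {
  s1 <- stratify_by_median(tibble::tibble(v = c(1, 2, 3, 4)), v)
  expect_equal(s1$threshold, 2.5)
  expect_setequal(s1$small_ids, c("1", "2"))
  expect_setequal(s1$large_ids, c("3", "4"))

  s2 <- stratify_by_median(tibble::tibble(v = c(1, 2, 2, 3)), v)
  expect_equal(s2$threshold, 2)
  expect_length(s2$small_ids, 3)  # median-valued rows go small
  expect_length(s2$large_ids, 1)

  expect_error(stratify_by_median(tibble::tibble(v = c(2, 2, 2)), v),
               "constant")
  co <- generate_cohort(n_tumors = 100, seed = 0, rasterize = FALSE)
  s3 <- stratify_by_median(co$table, volume_cm3, id = tumor_id)
  expect_length(s3$small_ids, 50)
  expect_length(s3$large_ids, 50)
})

test_that("circularity variance test wires split and Levene together", {
  prof <- subtype_profile("irr", tau = 6, irregularity_base = 0.12,
                          irregularity_slope = 0.15, growth_coupling = 0.5,
                          imaging_times = c(1, 7, 14, 18))
  tc <- generate_biosphere_timecourse(prof, n_spheroids = 100, seed = 33,
                                      rasterize = FALSE)
  cv <- circularity_variance_test(tc)
  expect_lt(cv$test$p_value, 0.01)
  expect_gt(cv$test$group_variances[["large"]],
            cv$test$group_variances[["small"]])

  flat <- subtype_profile("flat", tau = 3, irregularity_base = 0.12,
                          imaging_times = c(3, 8, 16))
  tcf <- generate_biosphere_timecourse(flat, n_spheroids = 100, seed = 34,
                                       rasterize = FALSE)
  cvf <- circularity_variance_test(tcf)
  expect_gt(cvf$test$p_value, 0.01)

  expect_error(circularity_variance_test(tc[1:3, ]), "at least 4")
  td <- tidy(cv)
  expect_equal(td$n_small + td$n_large, 400)
})

test_that("size-independent irregularity rarely triggers the variance test", {
  flat <- subtype_profile("flat", tau = 3, irregularity_base = 0.12,
                          imaging_times = c(3, 8, 16))
  pvals <- vapply(1:40, function(s) {
    tc <- generate_biosphere_timecourse(flat, n_spheroids = 40,
                                        seed = 5000 + s, rasterize = FALSE,
                                        n_vertices = 512)
    circularity_variance_test(tc)$test$p_value
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.9)
})
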