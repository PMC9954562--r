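test_that("noiseless exponential data is recovered exactly", {
  cs <- generate_count_series(4e4, tau = 3, times = seq(0, 21, 3),
                              noise_cv = 0, seed = 1)
  # rounding to integer counts leaves ~1e-7 relative jitter; refit on exact
  exact <- tibble::tibble(time_d = seq(0, 21, 3),
                          cells = 4e4 * exp(seq(0, 21, 3) / 3))
  f <- fit_exponential(exact)
  expect_equal(f$tau, 3, tolerance = 1e-9)
  expect_equal(f$n0, 4e4, tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_equal(f$doubling_time, f$tau * log(2), tolerance = 1e-12)
  # integer-rounded generator output is still recovered to high accuracy
  expect_equal(fit_exponential(cs)$tau, 3, tolerance = 1e-5)
})

test_that("degenerate count series are rejected", {
  flat <- tibble::tibble(time_d = 0:4, cells = rep(100, 5))
  expect_error(fit_exponential(flat), "no exponential growth")
  expect_error(fit_exponential(flat[1:2, ]), "3 points")
  shrink <- tibble::tibble(time_d = 0:4, cells = round(100 * exp(-(0:4))))
  expect_error(fit_exponential(shrink), "no exponential growth")
})

test_that("time-shift invariance: tau does not depend on the time origin", {
  tt <- seq(0, 12, 2)
  cs <- tibble::tibble(time_d = tt, cells = 5e3 * exp(tt / 2.5))
  f1 <- fit_exponential(cs)
  f2 <- fit_exponential(dplyr::mutate(cs, time_d = time_d + 100))
  expect_equal(f1$tau, f2$tau, tolerance = 1e-9)
})

test_that("window selection keeps the exponential phase, drops the plateau", {
  tt <- seq(0, 27, 3)
  n <- 1e4 * pmin(exp(tt / 3), exp(15 / 3))
  ser <- tibble::tibble(time_d = tt, cells = round(n))
  w <- select_exponential_window(ser, min_points = 4)
  expect_equal(w[1], 0)
  expect_lte(w[2], 15 + 3)  # at most one sample past the phase boundary

  pure <- tibble::tibble(time_d = tt, cells = round(1e4 * exp(tt / 3)))
  expect_equal(select_exponential_window(pure, min_points = 4), c(0, 27))
  expect_equal(select_exponential_window(pure, min_points = length(tt)),
               c(0, 27))
  expect_error(select_exponential_window(pure[1:3, ], min_points = 4),
               "need >=")
})

test_that("tau recovery under multiplicative noise is unbiased and tight", {
  taus <- vapply(1:50, function(s) {
    cs <- generate_count_series(4e4, tau = 2, times = seq(0, 14, 2),
                                noise_cv = 0.05, seed = 1000 + s)
    fit_exponential(cs)$tau
  }, numeric(1))
  expect_lt(abs(mean(taus) - 2) / 2, 0.02)
  expect_lt(sqrt(mean((taus - 2)^2)) / 2, 0.05)
})

test_that("spherical predictions evaluate the growth laws and their identity", {
  pr <- spherical_prediction(tau = 3, d0 = 50, t0 = 0)
  expect_equal(predict_diameter(pr, 9), 50 * exp(1), tolerance = 1e-12)
  expect_equal(predict_diameter(pr, 0), 50, tolerance = 1e-15)
  pr2 <- spherical_prediction(tau = 3, A0 = 2000, t0 = 0)
  expect_equal(predict_area(pr2, 9), 2000 * exp(2), tolerance = 1e-12)
  expect_equal(predict_area(pr2, 0), 2000, tolerance = 1e-15)
  expect_error(predict_diameter(pr, -1), ">= t0")
  expect_error(spherical_prediction(tau = 3, d0 = 50, A0 = 1000),
               "inconsistent")

  # A(t)/A0 = (d(t)/d0)^2 across a (tau, t) grid
  for (tau in c(0.5, 2, 3, 7)) {
    p <- spherical_prediction(tau = tau, d0 = 40, t0 = 1)
    t <- seq(1, 25, length.out = 17)
    expect_equal(predict_area(p, t) * p$d0^2,
                 p$A0 * predict_diameter(p, t)^2,
                 tolerance = 1e-9)
  }
})

test_that("volume chain: cell-volume times count equals exponential volume law", {
  v_c <- 2000  # um^3 per cell
  n0 <- 4e4; tau <- 3; t0 <- 2
  t <- seq(2, 20, length.out = 13)
  n_t <- n0 * exp((t - t0) / tau)
  V_tot <- v_c * n_t
  V0 <- v_c * n0
  expect_equal(V_tot, V0 * exp((t - t0) / tau), tolerance = 1e-9)
})

test_that("compactness verdict separates tracking from lagging growth", {
  prof <- subtype_profile("track", tau = 3, irregularity_base = 0.1,
                          growth_coupling = 1, imaging_times = c(0, 5, 10))
  tc <- generate_biosphere_timecourse(prof, n_spheroids = 30, seed = 21,
                                      rasterize = FALSE)
  meas <- dplyr::select(tc, time_d, area_um2)
  rep1 <- compactness_report(meas, fit = 3)
  expect_equal(rep1$verdict, "compact")
  expect_true(all(rep1$table$kappa > 1 / 1.5 & rep1$table$kappa < 1.5))
  expect_equal(rep1$table$kappa[1], 1, tolerance = 1e-12)

  lag <- subtype_profile("lag", tau = 3, irregularity_base = 0.1,
                         growth_coupling = 0.5, imaging_times = c(0, 6, 12, 18))
  tc2 <- generate_biosphere_timecourse(lag, n_spheroids = 30, seed = 22,
                                       rasterize = FALSE)
  rep2 <- compactness_report(dplyr::select(tc2, time_d, area_um2), fit = 3)
  expect_equal(rep2$verdict, "non-compact")
  expect_true(all(diff(rep2$table$kappa) < 0))
})

test_that("compactness report enforces its preconditions", {
  one_time <- tibble::tibble(time_d = rep(0, 20), area_um2 = rnorm(20, 2000))
  expect_error(compactness_report(one_time, fit = 3), ">= 2 time points")
  sparse <- tibble::tibble(time_d = rep(c(0, 5), c(20, 3)),
                           area_um2 = rnorm(23, 2000))
  expect_error(compactness_report(sparse, fit = 3), ">= 10 objects")
  expect_error(compactness_report(sparse, fit = 3, kappa_star = 0.9),
               "kappa_star")
})

test_that("growth fit tidiers expose parameters and fit quality", {
  cs <- generate_count_series(4e4, tau = 3, noise_cv = 0.02, seed = 5)
  f <- fit_exponential(cs, window = "auto")
  td <- tidy(f)
  expect_setequal(td$term, c("n0", "tau", "doubling_time"))
  gl <- glance(f)
  expect_equal(gl$doubling_time, gl$tau * log(2), tolerance = 1e-12)
  expect_gte(gl$window_start, 0)
  expect_s3_class(autoplot(f), "ggplot")
})
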