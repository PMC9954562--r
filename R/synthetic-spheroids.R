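#' Subtype growth/shape profile
#'
#' Bundles the parameters that distinguish the two in-vitro phenotypes the
#' generators emulate: a proliferation e-folding time `tau`, a baseline
#' boundary irregularity, the rate at which irregularity grows with spheroid
#' area, and a coupling factor between the count-derived growth rate and the
#' spheroid size growth rate (1 = cluster size tracks cell number under
#' spherical growth; < 1 = structures lag the spherical prediction, i.e. the
#' loose, less compact phenotype).
#'
#' @param name profile label, e.g. `"mesenchymal-like"`.
#' @param tau proliferation e-folding time in days (> 0). Doubling time is
#'   `tau * log(2)`.
#' @param irregularity_base dimensionless boundary perturbation amplitude at
#'   the initial size (>= 0, < 0.9).
#' @param irregularity_slope mean increase in irregularity per doubling of
#'   spheroid area (dimensionless).
#' @param growth_coupling ratio of the spheroid diameter e-folding rate to
#'   the rate implied by the cell-count `tau` under spherical growth.
#' @param slope_heterogeneity spread of the per-spheroid irregularity-size
#'   coupling: each spheroid's effective slope is
#'   `irregularity_slope * u_i` with `u_i ~ U(1 - h, 1 + h)`. The mean
#'   irregularity law is unchanged, but `h > 0` lets sibling spheroids
#'   diverge in shape as they grow — the within-culture shape heterogeneity
#'   the irregular phenotype shows. In `[0, 1]`; default 1.
#' @param imaging_times days at which spheroid fields are imaged.
#' @return An object of class `subtype_profile`.
#' @export
subtype_profile <- function(name, tau, irregularity_base = 0.12,
                            irregularity_slope = 0, growth_coupling = 1,
                            slope_heterogeneity = 1,
                            imaging_times = c(3, 8, 16)) {
  if (tau <= 0) abort("`tau` must be > 0 (days).")
  if (irregularity_base < 0 || irregularity_base >= 0.9)
    abort("`irregularity_base` must be in [0, 0.9).")
  if (slope_heterogeneity < 0 || slope_heterogeneity > 1)
    abort("`slope_heterogeneity` must be in [0, 1].")
  structure(
    list(name = name, tau = tau,
         irregularity_base = irregularity_base,
         irregularity_slope = irregularity_slope,
         growth_coupling = growth_coupling,
         slope_heterogeneity = slope_heterogeneity,
         imaging_times = sort(imaging_times)),
    class = "subtype_profile")
}

#' @export
print.subtype_profile <- function(x, ...) {
  cat(sprintf(
    "<subtype_profile> %s: tau = %.3g d, irregularity %.2f + %.2f/doubling, coupling %.2f\n",
    x$name, x$tau, x$irregularity_base, x$irregularity_slope,
    x$growth_coupling))
  invisible(x)
}

# Random-phase Fourier boundary r(theta) = 1 + clip(irr * sum_k a_k cos(k theta + phi_k)).
# Modes 2..n_modes, raw amplitudes ~ N(0,1)/k, unit-normalised so that
# sum(a_k^2) = 1; the perturbation is clipped to +/- 0.95 so the radius stays
# positive and the boundary cannot self-intersect.
fourier_boundary <- function(irregularity, n_modes, seed) {
  ks <- seq(2L, n_modes)
  co <- withr::with_seed(as.integer(seed), {
    list(a = rnorm(length(ks)) / ks, phi = runif(length(ks), 0, 2 * pi))
  })
  nrm <- sqrt(sum(co$a^2))
  if (nrm > 0) co$a <- co$a / nrm
  force(irregularity)
  function(theta) {
    p <- 0
    for (i in seq_along(ks)) {
      p <- p + co$a[i] * cos(ks[i] * theta + co$phi[i])
    }
    1 + clip(irregularity * p, -0.95, 0.95)
  }
}

# Shoelace area and arc length of the polygon with vertices (r_i, theta_i),
# theta on a uniform grid over [0, 2pi).
polygon_measures <- function(r, theta) {
  x <- r * cos(theta); y <- r * sin(theta)
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  area <- abs(sum(x * yn - xn * y)) / 2
  perim <- sum(sqrt((xn - x)^2 + (yn - y)^2))
  list(area = area, perimeter = perim,
       circularity = 4 * pi * area / perim^2)
}

#' Measure an exact polygon (shoelace / arc-length oracle)
#'
#' Computes area, perimeter and circularity of a polygon given its vertex
#' coordinates, bypassing any rasterization. Used as the exact-geometry
#' reference for the raster estimators.
#'
#' @param x,y numeric vertex coordinates of a simple closed polygon
#'   (unclosed; the last vertex connects back to the first).
#' @return A tibble with `area`, `perimeter`, `circularity`.
#' @export
measure_polygon <- function(x, y) {
  if (length(x) < 3L || length(x) != length(y))
    abort("Need >= 3 (x, y) vertex pairs.")
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  area <- abs(sum(x * yn - xn * y)) / 2
  perim <- sum(sqrt((xn - x)^2 + (yn - y)^2))
  tibble(area = area, perimeter = perim,
         circularity = 4 * pi * area / perim^2)
}

#' Generate one synthetic spheroid mask with exact ground truth
#'
#' Draws a random-phase Fourier perturbation of a circle, scales it so the
#' continuous (4096-gon) area equals that of a disk with the requested
#' equivalent diameter, and rasterizes it at the given pixel size. The truth
#' record carries the exact polygon area, perimeter and circularity computed
#' before rasterization.
#'
#' @param equivalent_diameter target area-equivalent diameter in um.
#' @param irregularity boundary perturbation amplitude in `[0, 1)`; 0 gives
#'   a disk (truth circularity exactly 1).
#' @param pixel_size um per pixel.
#' @param n_modes highest Fourier mode of the perturbation (>= 2).
#' @param seed integer seed; same seed and parameters give a bit-identical
#'   mask.
#' @param object_id,time labels stored on the mask and truth record.
#' @param n_vertices angular sampling of the continuous boundary used for
#'   the truth polygon and the rasterization lookup.
#' @return A list with elements `mask` ([spheroid_mask]) and `truth` (one-row
#'   tibble: `object_id`, `time_d`, `diameter_um`, `area_um2`,
#'   `perimeter_um`, `circularity`, `irregularity`).
#' @export
generate_spheroid_mask <- function(equivalent_diameter, irregularity,
                                   pixel_size = 0.5, n_modes = 6L, seed,
                                   object_id = "sph1", time = NA_real_,
                                   n_vertices = 4096L) {
  if (equivalent_diameter < 4 * pixel_size)
    abort(sprintf(
      "`equivalent_diameter` (%.3g um) below resolvable minimum %.3g um (4 pixels).",
      equivalent_diameter, 4 * pixel_size))
  if (irregularity < 0 || irregularity >= 1)
    abort("`irregularity` must be in [0, 1).")
  if (n_modes < 2L) abort("`n_modes` must be >= 2.")

  rfun <- fourier_boundary(irregularity, n_modes, seed)
  theta <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  r_rel <- rfun(theta)

  pm_unit <- polygon_measures(r_rel, theta)
  target_area <- pi * equivalent_diameter^2 / 4
  r0 <- sqrt(target_area / pm_unit$area)

  truth <- tibble(
    object_id = object_id, time_d = time,
    diameter_um = equivalent_diameter,
    area_um2 = target_area,
    perimeter_um = pm_unit$perimeter * r0,
    circularity = pm_unit$circularity,
    irregularity = irregularity)

  mask <- rasterize_boundary(r_rel * r0, pixel_size)
  list(mask = spheroid_mask(mask, pixel_size, object_id, time), truth = truth)
}

# Rasterize a star-shaped boundary given radii (um) on a uniform theta grid.
# Pixel centres; a pixel is foreground iff its centre lies inside the
# (linearly theta-interpolated) boundary. Only the annulus between the
# minimal and maximal boundary radius needs interpolation.
rasterize_boundary <- function(r_um, pixel_size) {
  n <- length(r_um)
  rmax <- max(r_um); rmin <- min(r_um)
  half <- ceiling(rmax / pixel_size) + 2L
  npx <- 2L * half + 1L
  cx <- half + 1L
  gx <- (seq_len(npx) - cx) * pixel_size
  X <- matrix(gx, npx, npx)
  Y <- matrix(gx, npx, npx, byrow = TRUE)
  R <- sqrt(X^2 + Y^2)
  M <- R <= rmin
  ann <- which(R > rmin & R <= rmax)
  if (length(ann)) {
    th <- atan2(Y[ann], X[ann]) %% (2 * pi)
    pos <- th * n / (2 * pi)
    i0 <- floor(pos)
    fr <- pos - i0
    i1 <- (i0 %% n) + 1L
    i2 <- ((i0 + 1L) %% n) + 1L
    rb <- r_um[i1] * (1 - fr) + r_um[i2] * fr
    M[ann] <- R[ann] <= rb
  }
  M
}

#' Simulate a biosphere spheroid time course
#'
#' Generates a cohort of spheroids whose area-equivalent diameters follow the
#' spherical exponential growth law `d(t) = d0 * exp(c * (t - t0) / (3 tau))`
#' (with `c` the profile's growth coupling) and whose boundary irregularity
#' evolves as `irregularity_base + u_i * irregularity_slope *
#' log2(A(t)/A(t0))`, clipped to `[0, 0.9)`, where `u_i` is the spheroid's
#' coupling-heterogeneity factor (see [subtype_profile()]; mean 1). Initial
#' diameters are drawn from a truncated normal distribution. Each
#' (spheroid, time) pair gets an independently seeded random boundary.
#'
#' @param profile a [subtype_profile].
#' @param n_spheroids number of spheroids per time point.
#' @param times imaging times in days (ascending); defaults to the profile's
#'   `imaging_times`. The first entry is the reference time `t0`.
#' @param d0_mean,d0_sd mean and sd of the initial equivalent diameter (um);
#'   draws are truncated below at `max(20, 8 * pixel_size)` um.
#' @param pixel_size um per pixel for rasterization.
#' @param n_modes highest Fourier mode of the boundary perturbation.
#' @param seed integer seed for the whole time course.
#' @param rasterize if `FALSE`, only the continuous-geometry truth table is
#'   produced (no masks); useful for large calibration sweeps.
#' @param n_vertices angular sampling of each truth polygon.
#' @return A tibble with one row per spheroid per time:
#'   `object_id`, `time_d`, `d0_um`, `diameter_um`, `area_um2`,
#'   `perimeter_um`, `circularity`, `irregularity`, and (if rasterized) a
#'   `mask` list-column of [spheroid_mask] objects.
#' @export
generate_biosphere_timecourse <- function(profile, n_spheroids = 200L,
                                          times = NULL,
                                          d0_mean = 40, d0_sd = 8,
                                          pixel_size = 0.5, n_modes = 6L,
                                          seed, rasterize = TRUE,
                                          n_vertices = 4096L) {
  times <- times %||% profile$imaging_times
  if (length(times) == 0L) abort("`times` must be a non-empty day list.")
  if (is.unsorted(times)) abort("`times` must be sorted ascending.")
  if (n_spheroids < 1L) abort("`n_spheroids` must be >= 1.")

  t0 <- times[1]
  nT <- length(times)
  d_min <- max(20, 8 * pixel_size)
  h <- profile$slope_heterogeneity %||% 0
  rng <- withr::with_seed(as.integer(seed), {
    list(d0 = pmax(rnorm(n_spheroids, d0_mean, d0_sd), d_min),
         u = runif(n_spheroids, 1 - h, 1 + h),
         sub = sample.int(.Machine$integer.max, n_spheroids * nT))
  })

  grid <- tidyr::expand_grid(i = seq_len(n_spheroids), t = times)
  d0 <- rng$d0[grid$i]
  dia <- d0 * exp(profile$growth_coupling * (grid$t - t0) / (3 * profile$tau))
  area_ratio <- (dia / d0)^2
  irr <- clip(profile$irregularity_base +
                rng$u[grid$i] * profile$irregularity_slope * log2(area_ratio),
              0, 0.8999)

  out <- purrr::pmap(
    list(grid$i, grid$t, dia, irr, seq_len(nrow(grid))),
    function(i, t, d, a, row) {
      id <- sprintf("%s_sph%03d", profile$name, i)
      g <- generate_spheroid_mask(d, a, pixel_size, n_modes,
                                  seed = rng$sub[row], object_id = id,
                                  time = t, n_vertices = n_vertices)
      if (!rasterize) g$mask <- NULL
      g
    })

  truth <- dplyr::bind_rows(purrr::map(out, "truth"))
  truth$d0_um <- d0
  truth <- dplyr::relocate(truth, "d0_um", .after = "time_d")
  if (rasterize) truth$mask <- purrr::map(out, "mask")
  truth
}

#' Simulate a cell-count growth series
#'
#' Counts follow `n(t) = n0 * exp((t - t0) / tau)` with optional
#' multiplicative lognormal noise of coefficient of variation `noise_cv`
#' (unit mean), rounded to integers with floor 1. `t0` is the first time.
#'
#' @param n0 initial cell count per biosphere (>= 1).
#' @param tau e-folding time in days (> 0).
#' @param times sampling times in days.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (>= 0; 0 gives a deterministic series).
#' @param seed integer seed.
#' @param culture_id,replicate_id labels for the output table.
#' @return A tibble: `culture_id`, `replicate_id`, `time_d`, `cells`.
#' @export
generate_count_series <- function(n0 = 4e4, tau, times = seq(0, 21, by = 3),
                                  noise_cv = 0.05, seed = 1L,
                                  culture_id = "culture1",
                                  replicate_id = "rep1") {
  if (n0 < 1) abort("`n0` must be >= 1 cells.")
  if (tau <= 0) abort("`tau` must be > 0 days.")
  if (noise_cv < 0) abort("`noise_cv` must be >= 0.")
  if (length(times) == 0L) abort("`times` must be non-empty.")
  t0 <- times[1]
  mu <- n0 * exp((times - t0) / tau)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    fac <- withr::with_seed(as.integer(seed),
                            rlnorm(length(times), -sdlog^2 / 2, sdlog))
    mu <- mu * fac
  }
  tibble(culture_id = culture_id, replicate_id = replicate_id,
         time_d = as.numeric(times), cells = pmax(1, round(mu)))
}

#' Compose a field image from generated spheroids
#'
#' Places independently generated spheroid masks on a flat background at
#' non-overlapping random positions, yielding a grayscale image (foreground
#' intensity 1, background 0, optional additive Gaussian noise) plus the
#' ground-truth masks in field coordinates. Intended for exercising
#' [segment_spheroids()] against known objects.
#'
#' @param n_spheroids number of objects to place.
#' @param diameter_mean,diameter_sd equivalent-diameter distribution (um).
#' @param irregularity boundary irregularity for every object.
#' @param pixel_size um per pixel.
#' @param field_size_um side length of the square field (um).
#' @param noise_sd additive Gaussian intensity noise sd.
#' @param seed integer seed.
#' @return A list: `image` (numeric matrix), `pixel_size`, `truth`
#'   (tibble of per-object truth with field-pixel offsets `off_row`,
#'   `off_col`), `masks` (list of [spheroid_mask]).
#' @export
generate_spheroid_field <- function(n_spheroids = 20L, diameter_mean = 60,
                                    diameter_sd = 10, irregularity = 0.2,
                                    pixel_size = 0.5, field_size_um = 1000,
                                    noise_sd = 0, seed = 1L) {
  npx <- ceiling(field_size_um / pixel_size)
  rng <- withr::with_seed(as.integer(seed), {
    list(d = pmax(rnorm(n_spheroids, diameter_mean, diameter_sd), 20),
         sub = sample.int(.Machine$integer.max, n_spheroids + 1L),
         u = matrix(runif(2L * n_spheroids * 50L), ncol = 2L))
  })
  img <- matrix(0, npx, npx)
  occupied <- matrix(FALSE, npx, npx)
  masks <- list(); truths <- list()
  ui <- 1L
  for (i in seq_len(n_spheroids)) {
    g <- generate_spheroid_mask(rng$d[i], irregularity, pixel_size,
                                seed = rng$sub[i],
                                object_id = sprintf("obj%03d", i))
    m <- g$mask$pixels
    placed <- FALSE
    for (try in 1:50) {
      if (ui > nrow(rng$u)) break
      orow <- 1L + floor(rng$u[ui, 1] * (npx - nrow(m) - 2L))
      ocol <- 1L + floor(rng$u[ui, 2] * (npx - ncol(m) - 2L))
      ui <- ui + 1L
      rr <- orow + seq_len(nrow(m)); cc <- ocol + seq_len(ncol(m))
      if (!any(occupied[rr, cc] & TRUE)) {
        # demand a 1-px clearance so neighbours never 8-touch
        sub <- occupied[(min(rr) - 1L):(max(rr) + 1L),
                        (min(cc) - 1L):(max(cc) + 1L)]
        if (!any(sub)) {
          img[rr, cc][m] <- 1
          occupied[rr, cc] <- occupied[rr, cc] | m
          g$truth$off_row <- orow; g$truth$off_col <- ocol
          masks[[length(masks) + 1L]] <- g$mask
          truths[[length(truths) + 1L]] <- g$truth
          placed <- TRUE
          break
        }
      }
    }
    if (!placed)
      warn(sprintf("could not place object %d without overlap; skipped", i))
  }
  if (noise_sd > 0) {
    img <- img + withr::with_seed(as.integer(rng$sub[n_spheroids + 1L]),
                                  matrix(rnorm(npx * npx, 0, noise_sd),
                                         npx, npx))
  }
  list(image = img, pixel_size = pixel_size,
       truth = dplyr::bind_rows(truths), masks = masks)
}
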