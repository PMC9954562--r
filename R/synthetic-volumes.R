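# Band-limited isotropic random field on the unit sphere: a sum of J
# plane-wave cosines with random directions, frequencies in [wmin, wmax] and
# amplitudes ~ N(0,1)/sqrt(w). The field is normalised to max |f| = 1 on a
# fine quadrature grid so that `irregularity` scales the peak radial
# perturbation directly (monotone in irregularity at fixed seed).
sphere_field <- function(seed, n_waves = 24L, wmin = 4, wmax = 14) {
  withr::with_seed(as.integer(seed), {
    v <- matrix(rnorm(3L * n_waves), n_waves, 3L)
    v <- v / sqrt(rowSums(v^2))
    w <- runif(n_waves, wmin, wmax)
    list(v = v, w = w,
         amp = rnorm(n_waves) / sqrt(w),
         phi = runif(n_waves, 0, 2 * pi))
  })
}

eval_sphere_field <- function(f, U) {
  s <- numeric(nrow(U))
  for (j in seq_along(f$w)) {
    s <- s + f$amp[j] * cos(f$w[j] * drop(U %*% f$v[j, ]) + f$phi[j])
  }
  s
}

# Continuous-surface truth for r(theta, phi) = 1 + clip(irr * f / max|f|):
# volume and surface by spherical quadrature with finite-difference surface
# derivatives. Returns unit-radius V, S, sphericity, and the normaliser.
radial_truth <- function(field, irregularity, n_theta = 192L, n_phi = 384L) {
  th <- (seq_len(n_theta) - 0.5) * pi / n_theta
  ph <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  TH <- matrix(th, n_theta, n_phi)
  PH <- matrix(ph, n_theta, n_phi, byrow = TRUE)
  U <- cbind(c(sin(TH) * cos(PH)), c(sin(TH) * sin(PH)), c(cos(TH)))
  g <- eval_sphere_field(field, U)
  gmax <- max(abs(g))
  p <- if (gmax > 0) clip(irregularity * g / gmax, -0.9, 0.9) else 0
  r <- matrix(1 + p, n_theta, n_phi)
  dth <- pi / n_theta; dph <- 2 * pi / n_phi
  rth <- r * 0
  rth[2:(n_theta - 1), ] <- (r[3:n_theta, ] - r[1:(n_theta - 2), ]) / (2 * dth)
  rth[1, ] <- (r[2, ] - r[1, ]) / dth
  rth[n_theta, ] <- (r[n_theta, ] - r[n_theta - 1, ]) / dth
  rph <- (r[, c(2:n_phi, 1)] - r[, c(n_phi, 1:(n_phi - 1))]) / (2 * dph)
  sinTH <- sin(TH)
  V <- sum(r^3 / 3 * sinTH) * dth * dph
  S <- sum(r^2 * sinTH * sqrt(1 + (rth / r)^2 + (rph / (r * sinTH))^2)) *
    dth * dph
  list(V = V, S = S, sphericity = sphericity_from_vs(V, S), gmax = gmax)
}

#' Generate a synthetic 3D tumor mask with exact ground truth
#'
#' Radially perturbs a ball by a band-limited random field on the sphere,
#' scales it to the target volume, and voxelizes it on an isotropic grid.
#' Truth volume, surface and sphericity are computed on the continuous
#' surface by fine spherical quadrature before voxelization.
#'
#' @param target_volume target volume in cm^3 (> 0).
#' @param irregularity peak radial perturbation as a fraction of the mean
#'   radius, in `[0, 0.9]`; 0 gives a ball (truth sphericity exactly 1).
#' @param voxel_size voxel edge length in mm.
#' @param seed integer seed; identical seeds give identical volumes.
#' @param tumor_id label.
#' @param n_waves number of plane-wave components of the surface field.
#' @return A list with `volume` ([tumor_volume]) and `truth` (one-row tibble:
#'   `tumor_id`, `volume_cm3`, `surface_cm2`, `sphericity`, `irregularity`).
#' @export
generate_volume_mask <- function(target_volume, irregularity,
                                 voxel_size = 0.5, seed,
                                 tumor_id = "tumor1", n_waves = 24L) {
  if (target_volume <= 0) abort("`target_volume` must be > 0 cm^3.")
  if (irregularity < 0 || irregularity > 0.9)
    abort("`irregularity` must be in [0, 0.9].")
  r_ball_mm <- (3 * target_volume * 1000 / (4 * pi))^(1 / 3)
  if (2 * r_ball_mm / voxel_size < 16)
    abort(sprintf(
      "grid too coarse: %.3g cm^3 at %.3g mm spans < 16 voxels; need voxel_size <= %.3g mm.",
      target_volume, voxel_size, 2 * r_ball_mm / 16))

  field <- sphere_field(seed, n_waves)
  tr <- radial_truth(field, irregularity)
  r0 <- (target_volume * 1000 / tr$V)^(1 / 3)  # mm

  truth <- tibble(
    tumor_id = tumor_id,
    volume_cm3 = target_volume,
    surface_cm2 = tr$S * r0^2 / 100,
    sphericity = tr$sphericity,
    irregularity = irregularity)

  rmax <- r0 * (1 + min(0.9, irregularity))
  half <- ceiling(rmax / voxel_size) + 2L
  nvox <- 2L * half + 1L
  g <- (seq_len(nvox) - (half + 1L)) * voxel_size
  X <- array(g, c(nvox, nvox, nvox))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  R <- sqrt(X^2 + Y^2 + Z^2)
  rmin_rel <- 1 - min(0.9, irregularity)
  inside <- R <= r0 * rmin_rel
  shell <- which(R > r0 * rmin_rel & R <= r0 * (1 + min(0.9, irregularity)))
  if (length(shell)) {
    Rs <- R[shell]
    U <- cbind(X[shell], Y[shell], Z[shell]) / Rs
    gs <- eval_sphere_field(field, U)
    p <- if (tr$gmax > 0) clip(irregularity * gs / tr$gmax, -0.9, 0.9) else 0
    inside[shell] <- Rs <= r0 * (1 + p)
  }
  list(volume = tumor_volume(inside, voxel_size, tumor_id), truth = truth)
}

#' Generate a cohort of synthetic tumor volumes
#'
#' Volumes are drawn lognormal around a median; surface irregularity
#' increases with log-volume through `sphericity_volume_coupling`, so a
#' positive coupling makes larger tumors less spherical. Ground-truth
#' sphericity per tumor comes from the continuous surface.
#'
#' @param n_tumors cohort size (>= 2).
#' @param volume_median median volume in cm^3.
#' @param volume_log_sd sd of log volume.
#' @param sphericity_volume_coupling increase in irregularity per unit
#'   increase of natural-log volume (0 = no size-shape coupling).
#' @param irregularity_base irregularity of a median-volume tumor.
#' @param voxel_size voxel edge length in mm.
#' @param seed integer seed.
#' @param rasterize if `FALSE`, skip voxelization and return only the truth
#'   table (fast; used for calibration sweeps).
#' @param truth_quadrature `c(n_theta, n_phi)` spherical quadrature used for
#'   the continuous-surface truth in the `rasterize = FALSE` path.
#' @return A list: `table` (tibble: `tumor_id`, `volume_cm3`,
#'   `irregularity`, `sphericity_truth`) and `volumes` (list of
#'   [tumor_volume], or `NULL` when `rasterize = FALSE`).
#' @export
generate_cohort <- function(n_tumors = 100L, volume_median = 29.09,
                            volume_log_sd = 0.8,
                            sphericity_volume_coupling = 0.06,
                            irregularity_base = 0.72,
                            voxel_size = 1, seed = 1L, rasterize = TRUE,
                            truth_quadrature = c(192L, 384L)) {
  if (n_tumors < 2L) abort("`n_tumors` must be >= 2.")
  rng <- withr::with_seed(as.integer(seed), {
    list(vol = rlnorm(n_tumors, log(volume_median), volume_log_sd),
         sub = sample.int(.Machine$integer.max, n_tumors))
  })
  irr <- clip(irregularity_base + sphericity_volume_coupling *
                (log(rng$vol) - log(volume_median)), 0.05, 0.88)
  volumes <- if (rasterize) vector("list", n_tumors) else NULL
  sph <- numeric(n_tumors)
  for (i in seq_len(n_tumors)) {
    id <- sprintf("tumor%03d", i)
    if (rasterize) {
      g <- generate_volume_mask(rng$vol[i], irr[i], voxel_size,
                                seed = rng$sub[i], tumor_id = id)
      volumes[[i]] <- g$volume
      sph[i] <- g$truth$sphericity
    } else {
      tr <- radial_truth(sphere_field(rng$sub[i]), irr[i],
                         n_theta = truth_quadrature[1],
                         n_phi = truth_quadrature[2])
      sph[i] <- tr$sphericity
    }
  }
  list(table = tibble(tumor_id = sprintf("tumor%03d", seq_len(n_tumors)),
                      volume_cm3 = rng$vol, irregularity = irr,
                      sphericity_truth = sph),
       volumes = volumes)
}
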