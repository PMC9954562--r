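# programmatic fixtures: ideal rasterized solids

raster_disk <- function(radius_px, pixel_size = 1, margin = 3L) {
  n <- 2L * ceiling(radius_px) + 2L * margin + 1L
  cx <- (n + 1) / 2
  g <- seq_len(n) - cx
  M <- outer(g, g, function(x, y) x^2 + y^2 <= radius_px^2)
  spheroid_mask(M, pixel_size, object_id = "disk")
}

raster_square <- function(side_px, pixel_size = 1, margin = 3L) {
  n <- side_px + 2L * margin
  M <- matrix(FALSE, n, n)
  M[margin + seq_len(side_px), margin + seq_len(side_px)] <- TRUE
  spheroid_mask(M, pixel_size, object_id = "square")
}

raster_ball <- function(radius_vox, voxel_size = 1, margin = 4L) {
  n <- 2L * ceiling(radius_vox) + 2L * margin + 1L
  cx <- (n + 1) / 2
  g <- seq_len(n) - cx
  X <- array(g, c(n, n, n))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  tumor_volume(X^2 + Y^2 + Z^2 <= radius_vox^2, voxel_size, "ball")
}

raster_ellipsoid <- function(a_vox, b_vox, c_vox, voxel_size = 1,
                             margin = 4L) {
  n <- 2L * ceiling(max(a_vox, b_vox, c_vox)) + 2L * margin + 1L
  cx <- (n + 1) / 2
  g <- seq_len(n) - cx
  X <- array(g, c(n, n, n))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  tumor_volume((X / a_vox)^2 + (Y / b_vox)^2 + (Z / c_vox)^2 <= 1,
               voxel_size, "ellipsoid")
}

# brute-force two-sided exact Mann-Whitney p over all rank splits
mw_brute_force <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  vals <- c(a, b)
  rk <- rank(vals)
  U_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  Us <- apply(idx, 2, function(s) sum(rk[s]) - n1 * (n1 + 1) / 2)
  ple <- mean(Us <= U_obs)
  pge <- mean(Us >= U_obs)
  min(1, 2 * min(ple, pge))
}
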