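#' Spheroid mask object
#'
#' A binary pixel mask of a single spheroid together with its physical pixel
#' size. The foreground must form one connected component (8-connectivity);
#' this is asserted by [measure_shape()], not at construction, so that
#' segmentation intermediates can be represented too.
#'
#' @param pixels logical or 0/1 matrix, `TRUE`/1 = foreground.
#' @param pixel_size physical pixel size, micrometres per pixel.
#' @param object_id object label.
#' @param time imaging time in days, or `NA`.
#' @return An object of class `spheroid_mask`.
#' @export
spheroid_mask <- function(pixels, pixel_size, object_id = NA_character_,
                          time = NA_real_) {
  if (!is.matrix(pixels)) abort("`pixels` must be a matrix.")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    abort("`pixel_size` must be a single positive number (um/pixel).")
  structure(
    list(pixels = matrix(as.logical(pixels), nrow(pixels), ncol(pixels)),
         pixel_size = as.numeric(pixel_size),
         object_id = as.character(object_id),
         time = as.numeric(time)),
    class = "spheroid_mask")
}

#' @export
print.spheroid_mask <- function(x, ...) {
  cat(sprintf("<spheroid_mask> %s: %d x %d px @ %.3g um/px, %d fg px\n",
              x$object_id, nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              sum(x$pixels)))
  invisible(x)
}

#' Tumor volume object
#'
#' A binary voxel mask of one segmented tumor with isotropic voxel size.
#'
#' @param voxels logical or 0/1 3D array.
#' @param voxel_size voxel edge length in millimetres.
#' @param tumor_id tumor label.
#' @return An object of class `tumor_volume`.
#' @export
tumor_volume <- function(voxels, voxel_size, tumor_id = NA_character_) {
  if (!(is.array(voxels) && length(dim(voxels)) == 3L))
    abort("`voxels` must be a 3D array.")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    abort("`voxel_size` must be a single positive number (mm).")
  structure(
    list(voxels = array(as.logical(voxels), dim(voxels)),
         voxel_size = as.numeric(voxel_size),
         tumor_id = as.character(tumor_id)),
    class = "tumor_volume")
}

#' @export
print.tumor_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<tumor_volume> %s: %dx%dx%d vox @ %.3g mm, V = %.2f cm^3\n",
              x$tumor_id, d[1], d[2], d[3], x$voxel_size,
              sum(x$voxels) * x$voxel_size^3 / 1000))
  invisible(x)
}

# clip a numeric vector into [lo, hi]
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# draw reproducible sub-seeds without touching the caller's RNG state
draw_subseeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}
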