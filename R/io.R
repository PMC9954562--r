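#' Write a spheroid mask as TIFF with a JSON sidecar
#'
#' The mask is stored as a single-page 8-bit TIFF (0/255); pixel size and
#' labels go to `<path>.json`.
#'
#' @param mask a [spheroid_mask].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "spheroid_mask"))
  tiff::writeTIFF(mask$pixels * 1, path, bits.per.sample = 8L)
  jsonlite::write_json(
    list(pixel_size_um = mask$pixel_size, object_id = mask$object_id,
         time_d = mask$time),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a spheroid mask written by [write_mask_tiff()]
#'
#' @param path TIFF path; `<path>.json` must hold `pixel_size_um`.
#' @param pixel_size overrides the sidecar pixel size if given.
#' @return A [spheroid_mask].
#' @export
read_mask_tiff <- function(path, pixel_size = NULL) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
  else list()
  ps <- pixel_size %||% meta$pixel_size_um
  if (is.null(ps)) abort("pixel size not given and no sidecar JSON found.")
  spheroid_mask(img > 0.5, ps,
                object_id = meta$object_id %||% basename(path),
                time = meta$time_d %||% NA_real_)
}

#' Write a tumor volume as NIfTI
#'
#' Voxel size (mm) is recorded in the NIfTI header pixdim.
#'
#' @param volume a [tumor_volume].
#' @param path output path (`.nii` or `.nii.gz`; use `.nii` for text-free
#'   workflows).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "tumor_volume"))
  img <- RNifti::asNifti(volume$voxels * 1L,
                         pixdim = rep(volume$voxel_size, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a tumor volume from NIfTI
#'
#' @param path NIfTI path.
#' @param tumor_id label; defaults to the file name.
#' @return A [tumor_volume] (voxel size from the header pixdim).
#' @export
read_volume_nifti <- function(path, tumor_id = NULL) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1]
  tumor_volume(array(img > 0.5, dim(img)), vs,
               tumor_id %||% sub("\\.nii(\\.gz)?$", "", basename(path)))
}
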