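#' Segment spheroids in a grayscale field image
#'
#' Global threshold (fixed value or Otsu), hole filling, connected-component
#' labelling with 8-connectivity, then removal of components smaller than
#' `min_area` and of components touching the image border (their perimeter is
#' undefined). Returns one [spheroid_mask] per surviving component, cropped
#' to its bounding box with a one-pixel margin.
#'
#' @param image numeric matrix (grayscale intensities).
#' @param pixel_size um per pixel.
#' @param threshold numeric intensity threshold, or `"otsu"`.
#' @param min_area minimum object area in um^2.
#' @param time optional acquisition time (days) stamped on each mask.
#' @return A list of [spheroid_mask] objects (possibly empty; an empty result
#'   emits a warning, not an error).
#' @export
segment_spheroids <- function(image, pixel_size, threshold = "otsu",
                              min_area = 200, time = NA_real_) {
  if (!is.matrix(image) || length(image) == 0L)
    abort("`image` must be a non-empty numeric matrix.")
  if (min_area < 0) abort("`min_area` must be >= 0.")
  thr <- if (identical(threshold, "otsu")) {
    rng <- range(image)
    if (diff(rng) == 0) rng[1] + 1  # flat image: nothing above threshold
    else {
      sc <- (image - rng[1]) / diff(rng)
      EBImage::otsu(EBImage::Image(sc)) * diff(rng) + rng[1]
    }
  } else {
    as.numeric(threshold)
  }
  bw <- image > thr
  if (!any(bw)) {
    warn("segmentation found no foreground; returning empty list")
    return(list())
  }
  lab <- label_components8(bw)
  lab <- matrix(as.integer(EBImage::fillHull(EBImage::Image(lab))),
                nrow(lab), ncol(lab))
  ids <- sort(unique(lab[lab > 0L]))
  min_px <- min_area / pixel_size^2
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  out <- list()
  for (id in ids) {
    sel <- lab == id
    if (sum(sel) < min_px || id %in% border) next
    rr <- range(which(rowSums(sel) > 0))
    cc <- range(which(colSums(sel) > 0))
    r0 <- max(1, rr[1] - 1L); c0 <- max(1, cc[1] - 1L)
    sub <- sel[r0:min(nrow(sel), rr[2] + 1L),
               c0:min(ncol(sel), cc[2] + 1L), drop = FALSE]
    msk <- spheroid_mask(
      sub, pixel_size, object_id = sprintf("seg%03d", length(out) + 1L),
      time = time)
    attr(msk, "origin") <- c(r0, c0)  # crop offset in image coordinates
    out[[length(out) + 1L]] <- msk
  }
  if (length(out) == 0L)
    warn("no component survived the size/border filters; returning empty list")
  out
}

# 8-connected component labelling: EBImage::bwlabel is 4-connected, so merge
# labels that touch diagonally with a small union-find pass.
label_components8 <- function(bw) {
  lab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(bw * 1))),
                nrow(bw), ncol(bw))
  k <- max(lab)
  if (k <= 1L) return(lab)
  parent <- seq_len(k)
  findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc])))
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      a <- findp(pairs[r, 1]); b <- findp(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    roots <- vapply(seq_len(k), findp, integer(1))
    dense <- match(roots, sort(unique(roots)))
    lab[lab > 0L] <- dense[lab[lab > 0L]]
  }
  lab
}

# Crofton 4-direction perimeter (pixels). Counts 0/1 transitions along rows,
# columns and both diagonals of the zero-padded mask; the Cauchy-Crofton
# weights make the estimate exact for a disk in the continuum limit.
perimeter_crofton <- function(M) {
  M <- rbind(FALSE, cbind(FALSE, M, FALSE), FALSE)
  nr <- nrow(M); nc <- ncol(M)
  n_h <- sum(M[, -1] != M[, -nc])
  n_v <- sum(M[-1, ] != M[-nr, ])
  n_d1 <- sum(M[-1, -1] != M[-nr, -nc])
  n_d2 <- sum(M[-1, -nc] != M[-nr, -1])
  (pi / 8) * (n_h + n_v + (n_d1 + n_d2) / sqrt(2))
}

# Marching-squares subpixel contour length (pixels): length of the longest
# 0.5-level contour of the padded binary image. Overestimates smooth
# perimeters by a few percent (staircase chords); offered as the alternative
# convention.
perimeter_contour <- function(M) {
  Mp <- rbind(0, cbind(0, M * 1, 0), 0)
  cl <- contourLines(seq_len(nrow(Mp)), seq_len(ncol(Mp)), Mp, levels = 0.5)
  if (length(cl) == 0L) return(0)
  max(vapply(cl, function(cc) {
    x <- c(cc$x, cc$x[1]); y <- c(cc$y, cc$y[1])
    sum(sqrt(diff(x)^2 + diff(y)^2))
  }, numeric(1)))
}

# Feret (maximum caliper) diameter in pixels from the convex hull of
# foreground pixel centres.
feret_diameter <- function(M) {
  idx <- which(M, arr.ind = TRUE)
  if (nrow(idx) == 1L) return(1)
  h <- chull(idx[, 1], idx[, 2])
  pts <- idx[h, , drop = FALSE]
  max(sqrt(outer(pts[, 1], pts[, 1], "-")^2 +
             outer(pts[, 2], pts[, 2], "-")^2)) + 1
}

#' Measure 2D shape descriptors of one spheroid mask
#'
#' Area is the foreground pixel count times `pixel_size^2`; the perimeter
#' estimator is selectable (`"crofton"`, the default multi-directional
#' approximation, or `"contour"`, the marching-squares subpixel contour
#' length); circularity is `4 * pi * area / perimeter^2`, reported clipped at
#' 1 with the raw value retained; the equivalent diameter is
#' `2 * sqrt(area / pi)` and the Feret diameter is emitted as a diagnostic.
#'
#' @param mask a [spheroid_mask] with exactly one 8-connected foreground
#'   component of at least 4 pixels.
#' @param perimeter `"crofton"` or `"contour"`.
#' @return A one-row tibble: `object_id`, `time_d`, `area_um2`,
#'   `perimeter_um`, `eq_diameter_um`, `feret_um`, `circularity_raw`,
#'   `circularity`, `estimator`.
#' @export
measure_shape <- function(mask, perimeter = c("crofton", "contour")) {
  perimeter <- match.arg(perimeter)
  if (!inherits(mask, "spheroid_mask")) abort("`mask` must be a spheroid_mask.")
  M <- mask$pixels
  npx <- sum(M)
  if (npx == 0L) abort("mask is empty: no foreground pixels.")
  if (npx < 4L) abort("mask has fewer than 4 foreground pixels.")
  ncomp <- max(label_components8(M))
  if (ncomp != 1L)
    abort(sprintf("mask must contain exactly one connected component, found %d.",
                  ncomp))
  ps <- mask$pixel_size
  area <- npx * ps^2
  per <- switch(perimeter,
                crofton = perimeter_crofton(M),
                contour = perimeter_contour(M)) * ps
  raw <- 4 * pi * area / per^2
  tibble(object_id = mask$object_id, time_d = mask$time,
         area_um2 = area, perimeter_um = per,
         eq_diameter_um = 2 * sqrt(area / pi),
         feret_um = feret_diameter(M) * ps,
         circularity_raw = raw, circularity = min(raw, 1),
         estimator = perimeter)
}

#' Measure many masks into one table
#'
#' Applies [measure_shape()] to a list of masks or to the `mask` list-column
#' of a generator time-course tibble.
#'
#' @param masks list of [spheroid_mask] objects, or a tibble holding a `mask`
#'   list-column (e.g. from [generate_biosphere_timecourse()]).
#' @param perimeter perimeter estimator, see [measure_shape()].
#' @return A tibble with one row per mask.
#' @export
measure_shapes <- function(masks, perimeter = c("crofton", "contour")) {
  perimeter <- match.arg(perimeter)
  if (is.data.frame(masks)) {
    if (is.null(masks$mask))
      abort("data frame input must carry a `mask` list-column.")
    masks <- masks$mask
  }
  dplyr::bind_rows(purrr::map(masks, measure_shape, perimeter = perimeter))
}
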