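# Brightfield morphometry: spheroid diameter/eccentricity and the image-area
# percentage occupied by dissociated cells and satellite aggregates.
# Images are plain numeric matrices (rows = y, cols = x), intensities on an
# arbitrary scale; objects are dark on a bright background unless
# `invert = TRUE`.

rescale01 <- function(x) {
  r <- range(x, finite = TRUE)
  if (r[1] == r[2]) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

otsu_mask <- function(img) {
  # global two-class Otsu threshold; foreground = brighter class
  r <- range(img, finite = TRUE)
  if (r[1] == r[2]) return(matrix(FALSE, nrow(img), ncol(img)))
  x <- rescale01(img)
  th <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  x > th
}

#' Segment the main spheroid in a brightfield image
#'
#' Global two-class (Otsu) thresholding, hole filling, then selection of the
#' largest connected foreground component.
#'
#' @param image numeric matrix; a single dominant dark object on a bright
#'   background (set `invert = TRUE` for bright-on-dark data).
#' @param invert logical; flips the expected polarity.
#' @return logical matrix: the spheroid mask.
#' @export
segment_main_spheroid <- function(image, invert = FALSE) {
  stopifnot(is.matrix(image), is.numeric(image))
  work <- if (invert) image else max(image) - image
  fg <- otsu_mask(work)
  if (!any(fg)) stop("no foreground found after thresholding", call. = FALSE)
  fg <- EBImage::fillHull(EBImage::Image(fg)) > 0
  lab <- EBImage::bwlabel(EBImage::Image(fg))
  lab <- matrix(as.integer(lab), nrow(image), ncol(image))
  cnt <- tabulate(lab[lab > 0L])
  mask <- lab == which.max(cnt)
  mask
}

#' Measure spheroid diameter and eccentricity from a binary mask
#'
#' The diameter is the equivalent-circle diameter `2 * sqrt(area / pi)` in
#' micrometres. Eccentricity comes from the second central moments of the
#' mask: with principal-axis eigenvalues `l1 >= l2` of the pixel covariance,
#' `e = sqrt(1 - l2 / l1)`, which equals the analytic eccentricity for exact
#' ellipses and is 0 for a circle.
#'
#' @param mask logical matrix from [segment_main_spheroid()].
#' @param pixel_size_um physical pixel size in micrometres.
#' @return list of class `spheroid_morphometry`: `diameter_um`,
#'   `eccentricity`, `area_um2`, `area_px`, `centroid_px` (y, x).
#' @export
measure_diameter_eccentricity <- function(mask, pixel_size_um) {
  stopifnot(is.matrix(mask), pixel_size_um > 0)
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty mask", call. = FALSE)
  area_px <- length(idx)
  co <- arrayInd(idx, dim(mask))
  centroid <- colMeans(co)
  if (area_px > 1L) {
    cc <- sweep(co, 2, centroid)
    S <- crossprod(cc) / area_px
    ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ecc <- if (ev[1] <= 0) 0 else sqrt(max(0, 1 - ev[2] / ev[1]))
  } else ecc <- 0
  structure(list(
    diameter_um = 2 * sqrt(area_px / pi) * pixel_size_um,
    eccentricity = ecc,
    area_um2 = area_px * pixel_size_um^2,
    area_px = area_px,
    centroid_px = stats::setNames(centroid, c("y", "x"))
  ), class = "spheroid_morphometry")
}

#' Area percentage occupied by dissociated cells around a spheroid
#'
#' Smooths the image with a Gaussian filter, applies a global two-class Otsu
#' threshold, labels the foreground objects, discards every object that
#' intersects the main spheroid mask, and keeps the remaining objects whose
#' equivalent-circle diameter lies within `diameter_band_px`. The result is
#' the kept pixel area as a percentage of the whole image area.
#'
#' @param image numeric matrix (same polarity convention as
#'   [segment_main_spheroid()]).
#' @param main_mask logical matrix from [segment_main_spheroid()].
#' @param gaussian_sigma_px Gaussian smoothing sigma in pixels (0 disables
#'   smoothing).
#' @param diameter_band_px inclusive `c(min, max)` equivalent-diameter band in
#'   pixels; objects outside it are discarded.
#' @param invert logical; flips the expected polarity.
#' @return list of class `loose_cell_result`: `occupied_area_fraction`
#'   (percent of image area), `n_objects`, `object_areas_px`,
#'   `object_diameters_px`, `kept_mask` (logical matrix).
#' @export
measure_loose_cell_area <- function(image, main_mask,
                                    gaussian_sigma_px = 5,
                                    diameter_band_px = c(5, 200),
                                    invert = FALSE) {
  stopifnot(is.matrix(image), is.matrix(main_mask),
            identical(dim(image), dim(main_mask)))
  if (diameter_band_px[1] > diameter_band_px[2])
    stop("diameter band is inverted", call. = FALSE)
  work <- if (invert) image else max(image) - image
  if (gaussian_sigma_px > 0)
    work <- matrix(EBImage::imageData(EBImage::gblur(
      EBImage::Image(rescale01(work)), sigma = gaussian_sigma_px)),
      nrow(image), ncol(image))
  fg <- otsu_mask(work)
  lab <- EBImage::bwlabel(EBImage::Image(fg))
  lab <- matrix(as.integer(lab), nrow(image), ncol(image))

  if (max(lab) == 0L) {
    return(structure(list(occupied_area_fraction = 0, n_objects = 0L,
                          object_areas_px = numeric(0),
                          object_diameters_px = numeric(0),
                          kept_mask = matrix(FALSE, nrow(image), ncol(image))),
                     class = "loose_cell_result"))
  }
  touching_main <- unique(lab[main_mask & lab > 0L])
  areas <- tabulate(lab[lab > 0L])
  diam <- 2 * sqrt(areas / pi)
  keep_id <- setdiff(which(diam >= diameter_band_px[1] &
                             diam <= diameter_band_px[2]), touching_main)
  kept_mask <- array(lab %in% keep_id, dim(lab))
  structure(list(
    occupied_area_fraction = 100 * sum(kept_mask) / length(kept_mask),
    n_objects = length(keep_id),
    object_areas_px = areas[keep_id],
    object_diameters_px = diam[keep_id],
    kept_mask = kept_mask
  ), class = "loose_cell_result")
}
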