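# Cryosection differentiation quantification: focus-plane selection, channel
# segmentation, spheroid area, and the Involucrin/CK14 integrated-density
# ratio.

laplacian_2d <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  up <- img[c(1, seq_len(nr - 1)), ]
  dn <- img[c(seq_len(nr - 1) + 1, nr), ]
  lf <- img[, c(1, seq_len(nc - 1))]
  rt <- img[, c(seq_len(nc - 1) + 1, nc)]
  up + dn + lf + rt - 4 * img
}

#' Select and sum the most in-focus z-planes
#'
#' The per-plane focus score is the variance of a discrete Laplacian (the
#' 5-point stencil); the `n` highest-scoring planes, adjacent or not, are
#' summed pixelwise.
#'
#' @param zstack numeric 3D array, dim = (y, x, z).
#' @param n number of planes to keep (default 3).
#' @return list with `image` (the pixelwise sum of the selected planes),
#'   `selected` (sorted plane indices) and `focus_scores`.
#' @export
select_focused_planes <- function(zstack, n = 3) {
  check_volume(zstack)
  nz <- dim(zstack)[3]
  if (nz < n) stop(sprintf("stack depth %d < n = %d", nz, n), call. = FALSE)
  scores <- vapply(seq_len(nz),
                   function(k) stats::var(as.vector(laplacian_2d(zstack[, , k]))),
                   numeric(1))
  sel <- sort(order(scores, decreasing = TRUE)[seq_len(n)])
  img <- zstack[, , sel[1]]
  for (k in sel[-1]) img <- img + zstack[, , k]
  list(image = img, selected = sel, focus_scores = scores)
}

#' Segment a fluorescence channel of a summed cryosection image
#'
#' Median filter of the given radius followed by a global two-class Otsu
#' threshold; the bright class is the segment.
#'
#' @param image numeric matrix.
#' @param median_radius_px median-filter radius in pixels (0 disables).
#' @return logical matrix (the segment).
#' @export
segment_channel <- function(image, median_radius_px = 2) {
  stopifnot(is.matrix(image))
  r <- range(image, finite = TRUE)
  if (r[1] == r[2]) stop("constant image: no segment found", call. = FALSE)
  work <- rescale01(image)
  if (median_radius_px > 0)
    work <- matrix(EBImage::imageData(EBImage::medianFilter(
      EBImage::Image(work), size = median_radius_px)),
      nrow(image), ncol(image))
  th <- EBImage::otsu(EBImage::Image(work), range = c(0, 1))
  seg <- matrix(as.vector(work) > th, nrow(image), ncol(image))
  if (!any(seg)) stop("empty segment after thresholding", call. = FALSE)
  seg
}

#' Whole-spheroid area in a reference channel
#'
#' Global threshold, largest connected component, morphological closing and
#' hole filling; returns the pixel area of the resulting spheroid region.
#'
#' @param image numeric matrix (typically the summed Involucrin channel).
#' @param closing_radius_px radius of the closing brush in pixels.
#' @return list with `area_px` and `mask`.
#' @export
spheroid_area_2d <- function(image, closing_radius_px = 7) {
  stopifnot(is.matrix(image))
  fg <- otsu_mask(image)
  if (!any(fg)) stop("no spheroid found", call. = FALSE)
  lab <- EBImage::bwlabel(EBImage::Image(fg))
  lab <- matrix(as.integer(lab), nrow(image), ncol(image))
  cnt <- tabulate(lab[lab > 0L])
  mask <- lab == which.max(cnt)
  if (closing_radius_px > 0) {
    brush <- EBImage::makeBrush(2 * closing_radius_px + 1, shape = "disc")
    mask <- EBImage::closing(EBImage::Image(mask), brush) > 0
  }
  mask <- EBImage::fillHull(EBImage::Image(mask)) > 0
  list(area_px = sum(mask), mask = mask)
}

#' Integrated density of a channel segment
#'
#' Integrated density = mean intensity inside the segment times the segment
#' area normalized to the spheroid area. Algebraically this equals the sum of
#' segment intensities divided by the spheroid area.
#'
#' @param image numeric matrix (summed focused planes of one channel).
#' @param segment logical matrix from [segment_channel()].
#' @param spheroid_area_px spheroid area from [spheroid_area_2d()].
#' @param channel_name optional label carried into the result.
#' @return list of class `integrated_density`: `channel_name`,
#'   `mean_intensity`, `area_px`, `normalized_area`, `integrated_density`.
#' @export
integrated_density <- function(image, segment, spheroid_area_px,
                               channel_name = NA_character_) {
  stopifnot(is.matrix(image), is.matrix(segment),
            identical(dim(image), dim(segment)), spheroid_area_px > 0)
  a <- sum(segment)
  m <- if (a > 0) mean(image[segment]) else 0
  structure(list(channel_name = channel_name, mean_intensity = m,
                 area_px = a, normalized_area = a / spheroid_area_px,
                 integrated_density = m * a / spheroid_area_px),
            class = "integrated_density")
}

#' Differentiation ratio of two integrated densities
#'
#' @param involucrin,ck14 `integrated_density` objects from the same section.
#' @return `involucrin$integrated_density / ck14$integrated_density`.
#' @export
differentiation_ratio <- function(involucrin, ck14) {
  stopifnot(inherits(involucrin, "integrated_density"),
            inherits(ck14, "integrated_density"))
  if (ck14$integrated_density <= 0)
    stop("CK14 integrated density must be > 0", call. = FALSE)
  involucrin$integrated_density / ck14$integrated_density
}

#' Quantify one two-channel cryosection z-stack
#'
#' Convenience wrapper running the full chain: focus selection on each
#' channel, channel segmentation, spheroid area from the Involucrin channel,
#' integrated densities and their ratio.
#'
#' @param channel_a,channel_b numeric 3D arrays (Involucrin-like and
#'   CK14-like channel stacks).
#' @param n_planes number of focused planes to sum.
#' @param median_radius_px median-filter radius for segmentation.
#' @return list with `ratio`, `id_a`, `id_b`, `selected_planes`,
#'   `spheroid_area_px`.
#' @export
quantify_cryosection <- function(channel_a, channel_b, n_planes = 3,
                                 median_radius_px = 2) {
  check_same_grid(channel_a, channel_b)
  fa <- select_focused_planes(channel_a, n_planes)
  fb <- select_focused_planes(channel_b, n_planes)
  sph <- spheroid_area_2d(fa$image)
  seg_a <- segment_channel(fa$image, median_radius_px)
  seg_b <- segment_channel(fb$image, median_radius_px)
  id_a <- integrated_density(fa$image, seg_a, sph$area_px, "involucrin")
  id_b <- integrated_density(fb$image, seg_b, sph$area_px, "ck14")
  list(ratio = differentiation_ratio(id_a, id_b), id_a = id_a, id_b = id_b,
       selected_planes = fa$selected, spheroid_area_px = sph$area_px)
}
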