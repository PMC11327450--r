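#' @useDynLib spheroidquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

# Volumes are 3D arrays with dim = (y, x, z): a stack of image-plane matrices.
# Label volumes are integer arrays, 0 = background, positive integers = object
# ids. Voxel spacing is a named numeric vector in micrometres, e.g.
# c(z = 1, y = 0.473, x = 0.473); order of the names is free.

DEFAULT_SPACING <- c(z = 1.0, y = 0.473, x = 0.473)

check_volume <- function(x, name = deparse(substitute(x))) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(sprintf("`%s` must be a 3D array", name), call. = FALSE)
  invisible(x)
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("volumes do not share the same grid (dim mismatch)", call. = FALSE)
  invisible(TRUE)
}

#' Normalize a voxel-spacing vector
#'
#' Accepts a named numeric vector with names `z`, `y`, `x` (any order) or an
#' unnamed length-3 vector interpreted as (z, y, x), and returns it ordered
#' (y, x, z) to match the array dimension convention `dim = (y, x, z)`.
#'
#' @param spacing named or unnamed numeric length-3 vector of voxel edge
#'   lengths in micrometres.
#' @return numeric length-3 vector named `y`, `x`, `z`.
#' @export
normalize_spacing <- function(spacing) {
  if (is.null(spacing)) stop("voxel spacing is required (micrometres)", call. = FALSE)
  spacing <- unlist(spacing)
  if (length(spacing) != 3L || !is.numeric(spacing) || any(!is.finite(spacing)) ||
      any(spacing <= 0))
    stop("spacing must be 3 positive finite lengths (micrometres)", call. = FALSE)
  if (!is.null(names(spacing)) && all(c("z", "y", "x") %in% names(spacing))) {
    spacing <- spacing[c("y", "x", "z")]
  } else {
    spacing <- stats::setNames(spacing[c(2L, 3L, 1L)], c("y", "x", "z"))
  }
  spacing
}

voxel_volume_um3 <- function(spacing) prod(normalize_spacing(spacing))

# per-label voxel counts; returns named integer vector (names = label ids > 0)
label_counts <- function(labels) {
  v <- labels[labels > 0L]
  if (length(v) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- tabulate(v)
  ids <- which(tab > 0L)
  stats::setNames(tab[ids], ids)
}

#' Per-label centroids of a label volume, in micrometres
#'
#' Voxel centers sit at `(index - 0.5) * spacing`; the centroid of a label is
#' the mean of its voxel centers.
#'
#' @param labels integer 3D label array.
#' @param spacing voxel spacing in micrometres (see [normalize_spacing()]).
#' @return numeric matrix with columns `y`, `x`, `z` and rows named by label
#'   id.
#' @export
label_centroids_um <- function(labels, spacing) {
  spacing <- normalize_spacing(spacing)
  idx <- which(labels > 0L)
  if (length(idx) == 0L)
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("y", "x", "z"))))
  co <- arrayInd(idx, dim(labels))
  dt <- data.table(id = labels[idx],
                   y = (co[, 1] - 0.5) * spacing[["y"]],
                   x = (co[, 2] - 0.5) * spacing[["x"]],
                   z = (co[, 3] - 0.5) * spacing[["z"]])
  cen <- dt[, .(y = mean(y), x = mean(x), z = mean(z)), keyby = id]
  m <- as.matrix(cen[, .(y, x, z)])
  rownames(m) <- cen$id
  m
}

#' Binary dilation/erosion of a 3D mask with the connectivity-1 element
#'
#' `dilate_3d(mask, k)` is exactly `k` iterations of binary dilation with the
#' 6-neighborhood cross (connectivity 1); it is computed in one pass as a
#' city-block distance threshold, which is equivalent on the voxel grid.
#' `erode_3d` is its dual (dilation of the complement); voxels outside the
#' volume are treated as background, so erosion eats inward from the faces,
#' matching the usual zero-padded convention of iterated morphology.
#'
#' @param mask logical 3D array.
#' @param k non-negative integer number of iterations.
#' @return logical 3D array of the same dimensions.
#' @export
dilate_3d <- function(mask, k) {
  check_volume(mask)
  k <- as.integer(k)
  stopifnot(k >= 0L)
  if (k == 0L || !any(mask)) return(mask)
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  out <- cpp_l1_distance(mask, dim(mask), k) <= k
  dim(out) <- dim(mask)
  out
}

#' @rdname dilate_3d
#' @export
erode_3d <- function(mask, k) {
  check_volume(mask)
  k <- as.integer(k)
  stopifnot(k >= 0L)
  if (k == 0L) return(mask)
  # pad with one background layer so out-of-volume counts as background,
  # then dilate the complement and take the complement back
  dm <- dim(mask)
  comp <- array(TRUE, dm + 2L)
  comp[2:(dm[1] + 1L), 2:(dm[2] + 1L), 2:(dm[3] + 1L)] <- !mask
  kept <- cpp_l1_distance(comp, dim(comp), k) > k
  dim(kept) <- dim(comp)
  kept[2:(dm[1] + 1L), 2:(dm[2] + 1L), 2:(dm[3] + 1L)]
}

#' Label connected components of a 3D binary mask
#'
#' @param mask logical 3D array.
#' @param connectivity 1 for the 6-neighborhood (faces), 3 for the full
#'   26-neighborhood.
#' @return integer 3D array of component labels (0 = background).
#' @export
label_components_3d <- function(mask, connectivity = 1) {
  check_volume(mask)
  stopifnot(connectivity %in% c(1, 3))
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  lab <- cpp_label3d(mask, dim(mask), as.integer(connectivity))
  dim(lab) <- dim(mask)
  lab
}

#' Fill interior cavities of a 3D binary mask
#'
#' Background voxels not 6-connected to any volume face are interior holes and
#' are set to foreground.
#'
#' @param mask logical 3D array.
#' @return logical 3D array.
#' @export
fill_holes_3d <- function(mask) {
  check_volume(mask)
  bg <- label_components_3d(!mask, connectivity = 1)
  dm <- dim(mask)
  border <- unique(c(bg[c(1, dm[1]), , ], bg[, c(1, dm[2]), ], bg[, , c(1, dm[3])]))
  border <- border[border > 0L]
  holes <- bg > 0L & !(bg %in% border)
  mask | holes
}

#' Keep only the largest connected component of a mask
#'
#' Ties are broken towards the component whose first voxel comes earliest in
#' array order.
#'
#' @inheritParams fill_holes_3d
#' @param connectivity neighborhood used to define connectedness (1 or 3).
#' @return logical 3D array containing a single component.
#' @export
largest_component_3d <- function(mask, connectivity = 1) {
  lab <- label_components_3d(mask, connectivity)
  cnt <- label_counts(lab)
  if (length(cnt) == 0L) return(array(FALSE, dim(mask)))
  keep <- as.integer(names(cnt)[which.max(cnt)])
  lab == keep
}

#' Gaussian blur of a 3D volume
#'
#' Separable Gaussian convolution with reflected boundaries; `sigma` is
#' isotropic in voxel units.
#'
#' @param vol numeric 3D array.
#' @param sigma standard deviation in voxels; 0 returns the input unchanged.
#' @return numeric 3D array.
#' @export
gaussian_blur_3d <- function(vol, sigma) {
  check_volume(vol)
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma >= 0)
  if (sigma == 0) return(vol)
  if (!is.double(vol)) storage.mode(vol) <- "double"
  out <- cpp_blur3d(vol, dim(vol), sigma)
  dim(out) <- dim(vol)
  out
}
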