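# Spheroid-level volumetrics from a nuclei instance-label volume: physical
# volume filter, spheroid-mask reconstruction by iterated binary closing,
# nuclei density, void region and the Ki-67 proliferation index.

#' Filter nuclei by physical volume
#'
#' Nuclei with a volume of less than `v_min_um3` or greater than `v_max_um3`
#' are treated as debris or segmentation errors and removed (labels set to 0).
#' The bounds are inclusive: a nucleus of exactly `v_min_um3` is kept.
#'
#' @param nucleus_labels integer 3D array of nucleus instance labels.
#' @param spacing voxel spacing in micrometres (see [normalize_spacing()]).
#' @param v_min_um3,v_max_um3 inclusive volume band in cubic micrometres.
#' @return list with `labels` (filtered volume, surviving ids unchanged) and
#'   `records`: a data.frame with one row per input id (`id`, `volume_um3`,
#'   `centroid_y_um`, `centroid_x_um`, `centroid_z_um`, `passes_filter`).
#' @export
filter_nuclei <- function(nucleus_labels, spacing, v_min_um3 = 300,
                          v_max_um3 = 3000) {
  check_volume(nucleus_labels)
  if (v_min_um3 >= v_max_um3) stop("v_min must be < v_max", call. = FALSE)
  spacing <- normalize_spacing(spacing)
  vv <- voxel_volume_um3(spacing)
  cnt <- label_counts(nucleus_labels)
  if (length(cnt) == 0L)
    return(list(labels = nucleus_labels,
                records = data.frame(id = integer(0), volume_um3 = numeric(0),
                                     centroid_y_um = numeric(0),
                                     centroid_x_um = numeric(0),
                                     centroid_z_um = numeric(0),
                                     passes_filter = logical(0))))
  ids <- as.integer(names(cnt))
  vols <- as.numeric(cnt) * vv
  passes <- vols >= v_min_um3 & vols <= v_max_um3
  cen <- label_centroids_um(nucleus_labels, spacing)
  records <- data.frame(id = ids, volume_um3 = vols,
                        centroid_y_um = cen[as.character(ids), "y"],
                        centroid_x_um = cen[as.character(ids), "x"],
                        centroid_z_um = cen[as.character(ids), "z"],
                        passes_filter = passes, row.names = NULL)
  out <- nucleus_labels
  if (any(!passes)) {
    drop <- ids[!passes]
    out[out %in% drop] <- 0L
  }
  list(labels = out, records = records)
}

#' Reconstruct the spheroid mask from nuclei by iterated binary closing
#'
#' Applies `n_iterations` of binary dilation followed by the same number of
#' binary erosions with the connectivity-1 (6-neighborhood) structuring
#' element, closing the gaps between nuclei without enlarging the spheroid;
#' then fills any remaining interior holes and, if several unconnected
#' structures remain, keeps only the largest. Iterations run on the voxel
#' grid, so anisotropic spacings close anisotropically in physical units.
#'
#' @param nucleus_labels integer 3D label array (typically the filtered output
#'   of [filter_nuclei()]), or a logical mask.
#' @param n_iterations dilation/erosion iteration count.
#' @param connectivity structuring-element connectivity (1 = 6-neighborhood).
#' @return logical 3D array: a single connected, hole-free spheroid mask
#'   containing every input nuclear voxel.
#' @export
reconstruct_spheroid_mask <- function(nucleus_labels, n_iterations = 40,
                                      connectivity = 1) {
  check_volume(nucleus_labels)
  if (connectivity != 1)
    stop("only the connectivity-1 structuring element is supported", call. = FALSE)
  mask <- nucleus_labels > 0
  if (!any(mask)) stop("empty label volume", call. = FALSE)
  n_iterations <- as.integer(n_iterations)
  co <- arrayInd(which(mask), dim(mask))
  margin <- min(min(co) - 1L, min(t(dim(mask) - t(co))))
  if (margin < n_iterations + 5L)
    warning(sprintf(paste0("border margin (%d voxels) < n_iterations + 5 (%d): ",
                           "dilation clamps at the volume faces"),
                    margin, n_iterations + 5L), call. = FALSE)
  closed <- erode_3d(dilate_3d(mask, n_iterations), n_iterations)
  filled <- fill_holes_3d(closed)
  largest_component_3d(filled, connectivity = 1)
}

#' Spheroid volume, nuclei density and void region
#'
#' A nucleus counts as inside the spheroid when its centroid voxel lies in the
#' mask. Density is the number of inside nuclei divided by the mask volume;
#' the void region is the mask volume not covered by nuclear segmentation.
#'
#' @param mask logical 3D spheroid mask from [reconstruct_spheroid_mask()].
#' @param nucleus_labels integer 3D label array on the same grid.
#' @param spacing voxel spacing in micrometres.
#' @return list of class `spheroid_volumetrics`: `volume_um3`,
#'   `n_nuclei_inside`, `density_per_um3`, `density_per_1e5_um3`,
#'   `void_volume_um3`, `nuclear_volume_inside_um3`.
#' @export
compute_density_and_void <- function(mask, nucleus_labels, spacing) {
  check_volume(mask); check_volume(nucleus_labels)
  check_same_grid(mask, nucleus_labels)
  if (!any(mask)) stop("empty spheroid mask", call. = FALSE)
  spacing <- normalize_spacing(spacing)
  vv <- voxel_volume_um3(spacing)
  volume_um3 <- sum(mask) * vv

  cen <- label_centroids_um(nucleus_labels, spacing)
  n_inside <- 0L
  if (nrow(cen) > 0) {
    vox <- cbind(ceiling(cen[, "y"] / spacing[["y"]]),
                 ceiling(cen[, "x"] / spacing[["x"]]),
                 ceiling(cen[, "z"] / spacing[["z"]]))
    vox <- pmin(pmax(vox, 1L), matrix(rep(dim(mask), each = nrow(vox)), ncol = 3))
    n_inside <- sum(mask[vox])
  }
  nuclear_inside <- sum(nucleus_labels > 0L & mask) * vv
  structure(list(
    volume_um3 = volume_um3,
    n_nuclei_inside = as.integer(n_inside),
    density_per_um3 = n_inside / volume_um3,
    density_per_1e5_um3 = 1e5 * n_inside / volume_um3,
    void_volume_um3 = volume_um3 - nuclear_inside,
    nuclear_volume_inside_um3 = nuclear_inside
  ), class = "spheroid_volumetrics")
}

#' Ki-67 proliferation index
#'
#' @param n_ki67_positive number of Ki-67 positive cells.
#' @param n_nuclei total number of nuclei counted (>= 1).
#' @return percentage `100 * n_ki67_positive / n_nuclei`.
#' @export
ki67_fraction <- function(n_ki67_positive, n_nuclei) {
  if (n_nuclei < 1) stop("n_nuclei must be >= 1", call. = FALSE)
  if (n_ki67_positive < 0 || n_ki67_positive > n_nuclei)
    stop("n_ki67_positive must lie in [0, n_nuclei]", call. = FALSE)
  100 * n_ki67_positive / n_nuclei
}
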