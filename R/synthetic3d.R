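#' Specification for a synthetic 3D spheroid volume
#'
#' Collects and validates every parameter of the 3D generator. Defaults mirror
#' typical cleared-spheroid confocal acquisitions: anisotropic voxels of
#' 0.473 x 0.473 um laterally with a 1 um z-step, cells of ~6.5 um radius
#' packed inside a spheroid, a nucleus occupying half the cell volume, and a
#' YAP-like channel whose nuclear-to-cytoplasm (N/C) ratio varies linearly
#' with distance to the spheroid rim.
#'
#' @param seed integer seed; all generator randomness flows from it.
#' @param voxel_spacing_um voxel edge lengths in micrometres, named or ordered
#'   (z, y, x).
#' @param spheroid_radius_um spheroid radius in micrometres.
#' @param n_cells number of cells to pack.
#' @param cell_radius_um_mean,cell_radius_um_sd per-cell radius distribution
#'   (truncated normal, micrometres).
#' @param nucleus_volume_fraction fraction of each cell's volume occupied by
#'   its concentric nucleus, in (0, 1).
#' @param ki67_fraction fraction of cells that are Ki-67 positive, in [0, 1].
#' @param nc_ratio_center,nc_ratio_rim programmed N/C ratio at the spheroid
#'   center and at the rim; per-cell ratios interpolate linearly in
#'   distance-to-rim.
#' @param yap_cyto_intensity_center,yap_cyto_intensity_rim cytoplasmic signal
#'   amplitude (above background) at center and rim (a.u.).
#' @param background_level constant background offset added everywhere (a.u.).
#' @param noise_sd additive Gaussian noise standard deviation (a.u.).
#' @param blur_sigma_vox isotropic Gaussian blur applied to intensity
#'   channels, in voxels; 0 disables blurring.
#' @param margin_vox clear margin kept between any labeled voxel and every
#'   volume face, in voxels. The default 46 leaves room for 40 iterations of
#'   binary dilation without touching the border.
#' @return a validated list of class `synthetic_spec_3d`.
#' @export
synthetic_spec_3d <- function(seed = 1L,
                              voxel_spacing_um = c(z = 1.0, y = 0.473, x = 0.473),
                              spheroid_radius_um = 40,
                              n_cells = 35L,
                              cell_radius_um_mean = 6.5,
                              cell_radius_um_sd = 0.5,
                              nucleus_volume_fraction = 0.5,
                              ki67_fraction = 0.3,
                              nc_ratio_center = 1.0,
                              nc_ratio_rim = 2.0,
                              yap_cyto_intensity_center = 100,
                              yap_cyto_intensity_rim = 100,
                              background_level = 0,
                              noise_sd = 0,
                              blur_sigma_vox = 0,
                              margin_vox = 46L) {
  spacing <- normalize_spacing(voxel_spacing_um)
  stopifnot(
    length(seed) == 1L, is.finite(seed),
    spheroid_radius_um > 0,
    n_cells >= 1L,
    cell_radius_um_mean > 0, cell_radius_um_sd >= 0,
    nucleus_volume_fraction > 0, nucleus_volume_fraction < 1,
    ki67_fraction >= 0, ki67_fraction <= 1,
    nc_ratio_center > 0, nc_ratio_rim > 0,
    yap_cyto_intensity_center > 0, yap_cyto_intensity_rim > 0,
    background_level >= 0, noise_sd >= 0, blur_sigma_vox >= 0,
    margin_vox >= 0L
  )
  if (cell_radius_um_mean >= spheroid_radius_um)
    stop("cell radius must be smaller than the spheroid radius", call. = FALSE)
  structure(list(
    seed = as.integer(seed), spacing = spacing,
    spheroid_radius_um = spheroid_radius_um, n_cells = as.integer(n_cells),
    cell_radius_um_mean = cell_radius_um_mean,
    cell_radius_um_sd = cell_radius_um_sd,
    nucleus_volume_fraction = nucleus_volume_fraction,
    ki67_fraction = ki67_fraction,
    nc_ratio_center = nc_ratio_center, nc_ratio_rim = nc_ratio_rim,
    yap_cyto_intensity_center = yap_cyto_intensity_center,
    yap_cyto_intensity_rim = yap_cyto_intensity_rim,
    background_level = background_level, noise_sd = noise_sd,
    blur_sigma_vox = blur_sigma_vox, margin_vox = as.integer(margin_vox)
  ), class = "synthetic_spec_3d")
}

# rejection-sample non-overlapping sphere centers inside the spheroid.
# Physical coordinates relative to the spheroid center, columns y/x/z (um).
pack_cells <- function(R, radii, max_attempts_per_cell = 2000L) {
  n <- length(radii)
  centers <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("y", "x", "z")))
  placed <- 0L
  for (i in seq_len(n)) {
    r_max <- R - radii[i]
    if (r_max <= 0) break
    ok <- FALSE
    for (a in seq_len(max_attempts_per_cell)) {
      p <- stats::runif(3, -r_max, r_max)
      if (sum(p^2) > r_max^2) next
      if (placed > 0L) {
        d2 <- colSums((t(centers[seq_len(placed), , drop = FALSE]) - p)^2)
        if (any(d2 < (radii[seq_len(placed)] + radii[i])^2)) next
      }
      centers[i, ] <- p
      placed <- placed + 1L
      ok <- TRUE
      break
    }
    if (!ok) break
  }
  if (placed < n)
    stop(sprintf(paste0("could not pack %d cells of mean radius %.2f um into a ",
                        "spheroid of radius %.2f um (achieved %d); reduce n_cells ",
                        "or enlarge the spheroid"),
                 n, mean(radii), R, placed), call. = FALSE)
  centers
}

#' Generate a synthetic spheroid with ground truth
#'
#' Packs ellipsoidal (spherical in physical units) cells inside a spheroid by
#' rejection sampling, places a concentric nucleus in each, selects a Ki-67+
#' subpopulation, and renders three intensity channels: `dapi` (nuclear),
#' `yap` (with programmed per-cell N/C ratios) and `ki67`. With zero blur,
#' noise and background, the measured N/C ratio of every cell equals
#' `truth$true_nc_ratio` exactly.
#'
#' Label volumes share ids: nucleus and Ki-67 objects carry the id of their
#' parent cell. The ground-truth table reports, per cell: centroid (um, grid
#' coordinates), cell/nucleus volumes (um^3, voxel-counted), programmed N/C
#' ratio, Ki-67 status and true distance to the spheroid rim.
#'
#' @param spec a [synthetic_spec_3d()] object.
#' @return list of class `synthetic_spheroid` with elements `cell_labels`,
#'   `nucleus_labels`, `ki67_labels` (integer arrays), `channels` (named list
#'   of numeric arrays: `dapi`, `yap`, `ki67`), `truth` (data.frame), and
#'   `spacing`.
#' @export
generate_spheroid <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec_3d"))
  set.seed(spec$seed)
  sp <- spec$spacing            # (y, x, z) um
  R <- spec$spheroid_radius_um

  radii <- stats::rnorm(spec$n_cells, spec$cell_radius_um_mean, spec$cell_radius_um_sd)
  radii <- pmin(pmax(radii, 0.4 * spec$cell_radius_um_mean),
                min(2 * spec$cell_radius_um_mean, 0.9 * R))
  centers <- pack_cells(R, radii)

  # grid: spheroid centered, margin_vox clear voxels on every face
  half_vox <- ceiling(R / sp) + spec$margin_vox
  dm <- as.integer(2L * half_vox + 1L)
  names(dm) <- NULL
  center_um <- (half_vox + 0.5) * sp   # spheroid center in grid um coordinates

  cell_labels <- array(0L, dm)
  nucleus_labels <- array(0L, dm)
  nuc_scale <- spec$nucleus_volume_fraction^(1 / 3)

  ax_y <- (seq_len(dm[1]) - 0.5) * sp[["y"]]
  ax_x <- (seq_len(dm[2]) - 0.5) * sp[["x"]]
  ax_z <- (seq_len(dm[3]) - 0.5) * sp[["z"]]

  for (i in seq_len(nrow(centers))) {
    c_um <- centers[i, ] + center_um
    r <- radii[i]
    iy <- which(abs(ax_y - c_um[["y"]]) <= r)
    ix <- which(abs(ax_x - c_um[["x"]]) <= r)
    iz <- which(abs(ax_z - c_um[["z"]]) <= r)
    d2 <- outer(outer((ax_y[iy] - c_um[["y"]])^2, (ax_x[ix] - c_um[["x"]])^2, `+`),
                (ax_z[iz] - c_um[["z"]])^2, `+`)
    block <- cell_labels[iy, ix, iz]
    inside <- d2 <= r^2
    block[inside] <- i
    cell_labels[iy, ix, iz] <- block
    nblock <- nucleus_labels[iy, ix, iz]
    nblock[d2 <= (r * nuc_scale)^2] <- i
    nucleus_labels[iy, ix, iz] <- nblock
  }

  # Ki-67+ subpopulation, chosen uniformly; the Ki-67 object is the nucleus
  n_pos <- round(spec$ki67_fraction * spec$n_cells)
  pos_ids <- if (n_pos > 0) sort(sample.int(spec$n_cells, n_pos)) else integer(0)
  ki67_labels <- array(0L, dm)
  sel <- nucleus_labels %in% pos_ids & nucleus_labels > 0L
  ki67_labels[sel] <- nucleus_labels[sel]

  # programmed per-cell N/C ratio and cytoplasmic amplitude, linear in
  # distance-to-rim d (d = 0 at the rim, d = R at the center)
  d_rim <- R - sqrt(rowSums(centers^2))
  f <- d_rim / R
  nc_true <- spec$nc_ratio_rim + (spec$nc_ratio_center - spec$nc_ratio_rim) * f
  cyto_amp <- spec$yap_cyto_intensity_rim +
    (spec$yap_cyto_intensity_center - spec$yap_cyto_intensity_rim) * f

  lut_cyto <- c(0, cyto_amp)                  # index by label + 1
  lut_nuc <- c(0, cyto_amp * nc_true)
  yap <- spec$background_level + lut_cyto[cell_labels + 1L]
  dim(yap) <- dm
  in_nuc <- nucleus_labels > 0L
  yap[in_nuc] <- spec$background_level + lut_nuc[nucleus_labels[in_nuc] + 1L]

  dapi <- array(spec$background_level, dm)
  dapi[in_nuc] <- spec$background_level + 200
  ki67 <- array(spec$background_level, dm)
  ki67[ki67_labels > 0L] <- spec$background_level + 150

  channels <- list(dapi = dapi, yap = yap, ki67 = ki67)
  if (spec$blur_sigma_vox > 0)
    channels <- lapply(channels, gaussian_blur_3d, sigma = spec$blur_sigma_vox)
  if (spec$noise_sd > 0)
    channels <- lapply(channels, function(ch)
      ch + array(stats::rnorm(length(ch), 0, spec$noise_sd), dm))

  vox_nuc <- label_counts(nucleus_labels)
  vox_cell <- label_counts(cell_labels)
  vv <- voxel_volume_um3(sp)
  ids <- seq_len(spec$n_cells)
  truth <- data.frame(
    id = ids,
    centroid_y_um = centers[, "y"] + center_um[["y"]],
    centroid_x_um = centers[, "x"] + center_um[["x"]],
    centroid_z_um = centers[, "z"] + center_um[["z"]],
    cell_volume_um3 = as.numeric(vox_cell[as.character(ids)]) * vv,
    nucleus_volume_um3 = as.numeric(vox_nuc[as.character(ids)]) * vv,
    true_nc_ratio = nc_true,
    ki67_status = ids %in% pos_ids,
    true_distance_to_rim_um = d_rim
  )

  structure(list(cell_labels = cell_labels, nucleus_labels = nucleus_labels,
                 ki67_labels = ki67_labels, channels = channels, truth = truth,
                 spacing = sp, center_um = center_um,
                 spheroid_radius_um = R),
            class = "synthetic_spheroid")
}
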