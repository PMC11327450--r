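# Volume I/O and the end-to-end orchestration of generator -> volumetrics ->
# subcellular -> spatial with a reproducibility manifest.
#
# Volumes travel as multi-page 32-bit TIFF plus a JSON sidecar
# (<name>.tif + <name>.tif.json) holding the voxel spacing (micrometres),
# the intensity scale/offset and the payload type ("labels" or "intensity").
# TIFF samples are stored on [0, 1] and rescaled on read; the float32 mantissa
# keeps label round-trips exact for ids into the millions.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a 3D volume as multi-page TIFF with a JSON spacing sidecar
#'
#' @param vol 3D array, integer labels or numeric intensities, dim = (y, x, z).
#' @param path output file path (.tif).
#' @param spacing voxel spacing in micrometres (see [normalize_spacing()]).
#' @param type `"labels"` or `"intensity"`; defaults by storage mode.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, spacing,
                         type = if (is.integer(vol)) "labels" else "intensity") {
  check_volume(vol)
  type <- match.arg(type, c("labels", "intensity"))
  spacing <- normalize_spacing(spacing)
  if (type == "labels" && any(vol %% 1 != 0))
    stop("non-integer data cannot be written as labels", call. = FALSE)
  offset <- min(vol, 0)
  scale <- max(max(vol) - offset, 1)
  pages <- lapply(seq_len(dim(vol)[3]),
                  function(k) (vol[, , k] - offset) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta <- list(spacing_um = as.list(spacing[c("z", "y", "x")]),
               scale = scale, offset = offset, type = type,
               dim = dim(vol))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a 3D volume written by [write_volume()]
#'
#' @param path TIFF path.
#' @param expect `"labels"` or `"intensity"`; requesting labels from an
#'   intensity payload (or non-integer data) is an error.
#' @param spacing optional spacing override; otherwise the sidecar value is
#'   used. Spacing missing in both places is an error, since downstream
#'   operations are in physical units.
#' @return 3D array (integer for labels) with attribute `spacing_um`
#'   (named y/x/z vector in micrometres).
#' @export
read_volume <- function(path, expect = c("intensity", "labels"), spacing = NULL) {
  expect <- match.arg(expect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  meta <- if (file.exists(sidecar_path(path)))
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE) else NULL
  scale <- if (!is.null(meta$scale)) meta$scale else 1
  offset <- if (!is.null(meta$offset)) meta$offset else 0

  vol <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) vol[, , k] <- pages[[k]]
  vol <- vol * scale + offset

  if (expect == "labels") {
    if (!is.null(meta$type) && meta$type != "labels")
      stop("label volume expected but the file holds intensity data", call. = FALSE)
    ivol <- round(vol)
    if (max(abs(vol - ivol)) > 1e-3)
      stop("label volume expected but the payload is not integer-valued", call. = FALSE)
    vol <- array(as.integer(ivol), dim(vol))
  }

  if (is.null(spacing)) {
    if (is.null(meta$spacing_um))
      stop("no voxel spacing: none stored with the file and no override given",
           call. = FALSE)
    spacing <- unlist(meta$spacing_um)
  }
  attr(vol, "spacing_um") <- normalize_spacing(spacing)
  vol
}

# ---- run configuration ----------------------------------------------------

default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    synthetic = list(
      voxel_spacing_um = c(z = 1.0, y = 0.473, x = 0.473),
      spheroid_radius_um = 36, n_cells = 25L,
      cell_radius_um_mean = 6.5, cell_radius_um_sd = 0.5,
      nucleus_volume_fraction = 0.5, ki67_fraction = 0.3,
      nc_ratio_center = 1.0, nc_ratio_rim = 2.0,
      yap_cyto_intensity_center = 100, yap_cyto_intensity_rim = 100,
      background_level = 10, noise_sd = 0, blur_sigma_vox = 0),
    volumetrics = list(v_min_um3 = 300, v_max_um3 = 3000, n_iterations = 40L),
    subcellular = list(threshold = 0.5, metric = "nucleus_coverage",
                       channel = "yap"),
    spatial = list(n_bins = 10L),
    write_volumes = FALSE
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop(sprintf("unknown config key: %s", full), call. = FALSE)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], as.list(user[[key]]), full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Read and resolve a run configuration
#'
#' Accepts a YAML file path or a named list of overrides; unknown keys are
#' rejected. Values not given fall back to the package defaults (a 50-cell,
#' 30 um-radius spheroid with a rim-high programmed N/C gradient).
#'
#' @param config NULL, a YAML file path, or a named list.
#' @return the fully resolved configuration list.
#' @export
read_run_config <- function(config = NULL) {
  defaults <- default_run_config()
  if (is.null(config)) return(defaults)
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config),
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  merge_config(defaults, config)
}

#' Run the full synthetic-spheroid quantification chain
#'
#' Executes generator -> nuclei volume filter -> spheroid-mask reconstruction
#' -> density/void -> nucleus-cell matching -> cytoplasm -> background-
#' corrected N/C ratios -> Ki-67 assignment -> convex-hull distances ->
#' radial profile, writing per-stage CSV tables, the resolved configuration
#' and a reproducibility manifest into `out_dir`.
#'
#' The manifest (manifest.json) holds the package version, a hash of the
#' resolved configuration and the SHA-256 checksum of every output file; it
#' contains no wall-clock fields, so identical configurations reproduce
#' byte-identical manifests. Timing goes to run_log.json instead.
#'
#' @param config NULL, YAML path or named list (see [read_run_config()]).
#' @param out_dir output directory (created if needed); overrides
#'   `config$out_dir`.
#' @return the manifest, invisibly; all tables are also returned in the
#'   `tables` attribute-free list element of the result.
#' @export
run_all <- function(config = NULL, out_dir = NULL) {
  cfg <- read_run_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (is.null(cfg$out_dir)) stop("an output directory is required", call. = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage <- "simulate"
  res <- tryCatch({
    spec <- do.call(synthetic_spec_3d,
                    c(list(seed = cfg$seed), cfg$synthetic))
    syn <- generate_spheroid(spec)

    stage <- "volumetrics3d"
    flt <- filter_nuclei(syn$nucleus_labels, syn$spacing,
                         cfg$volumetrics$v_min_um3, cfg$volumetrics$v_max_um3)
    mask <- reconstruct_spheroid_mask(flt$labels,
                                      n_iterations = cfg$volumetrics$n_iterations)
    volm <- compute_density_and_void(mask, flt$labels, syn$spacing)
    ki <- assign_ki67(syn$ki67_labels, syn$cell_labels)
    ki_pct <- ki67_fraction(sum(ki), length(ki))

    stage <- "subcellular"
    ch <- syn$channels[[cfg$subcellular$channel]]
    matches <- match_nuclei_to_cells(syn$nucleus_labels, syn$cell_labels,
                                     threshold = cfg$subcellular$threshold,
                                     metric = cfg$subcellular$metric)
    cyto <- derive_cytoplasm(syn$cell_labels, syn$nucleus_labels, matches)
    bg <- background_level(ch, syn$cell_labels)
    cm <- compartment_means_and_ratio(ch, syn$nucleus_labels,
                                      cyto$cytoplasm_labels, matches, bg,
                                      syn$spacing, ki67_status = ki)

    stage <- "spatial"
    cen <- label_centroids_um(syn$nucleus_labels, syn$spacing)
    sprec <- spatial_records(cm$records, cen)
    prof <- radial_profile(sprec$records, n_bins = cfg$spatial$n_bins)

    stage <- "write"
    vol_row <- data.frame(
      n_nuclei_total = nrow(flt$records),
      n_nuclei_pass = sum(flt$records$passes_filter),
      spheroid_volume_um3 = volm$volume_um3,
      n_nuclei_inside = volm$n_nuclei_inside,
      density_per_um3 = volm$density_per_um3,
      void_volume_um3 = volm$void_volume_um3,
      ki67_positive_pct = ki_pct)
    paths <- c(per_cell = file.path(cfg$out_dir, "per_cell.csv"),
               volumetrics = file.path(cfg$out_dir, "volumetrics.csv"),
               radial_profile = file.path(cfg$out_dir, "radial_profile.csv"),
               nuclei = file.path(cfg$out_dir, "nuclei_records.csv"),
               config = file.path(cfg$out_dir, "config_resolved.yaml"))
    write.csv(sprec$records, paths[["per_cell"]], row.names = FALSE)
    write.csv(vol_row, paths[["volumetrics"]], row.names = FALSE)
    write.csv(prof, paths[["radial_profile"]], row.names = FALSE)
    write.csv(flt$records, paths[["nuclei"]], row.names = FALSE)
    cfg_out <- cfg
    cfg_out$out_dir <- NULL   # run metadata, not configuration
    cfg_out$synthetic$voxel_spacing_um <- as.list(cfg$synthetic$voxel_spacing_um)
    yaml::write_yaml(cfg_out, paths[["config"]])
    if (isTRUE(cfg$write_volumes)) {
      vol_paths <- c(nucleus_labels = file.path(cfg$out_dir, "nucleus_labels.tif"),
                     cell_labels = file.path(cfg$out_dir, "cell_labels.tif"),
                     spheroid_mask = file.path(cfg$out_dir, "spheroid_mask.tif"))
      write_volume(syn$nucleus_labels, vol_paths[["nucleus_labels"]], syn$spacing)
      write_volume(syn$cell_labels, vol_paths[["cell_labels"]], syn$spacing)
      write_volume(array(as.integer(mask), dim(mask)),
                   vol_paths[["spheroid_mask"]], syn$spacing)
      paths <- c(paths, vol_paths)
    }
    list(paths = paths,
         tables = list(per_cell = sprec$records, volumetrics = vol_row,
                       radial_profile = prof, nuclei = flt$records,
                       qc = cm$qc))
  }, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })

  checksums <- vapply(res$paths, function(p) digest::digest(file = p, algo = "sha256"),
                      character(1))
  cfg_hashed <- cfg
  cfg_hashed$out_dir <- NULL
  manifest <- list(
    tool = "spheroidquant",
    version = as.character(utils::packageVersion("spheroidquant")),
    config_hash = digest::digest(cfg_hashed, algo = "sha256"),
    files = as.list(checksums))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(list(started = format(t0, "%Y-%m-%dT%H:%M:%OS3"),
                            finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"),
                            elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
                       file.path(cfg$out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(manifest, list(tables = res$tables)))
}
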