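#!/usr/bin/env Rscript
# Generate the synthetic datasets used by the downstream analysis scripts:
# a 3D cleared-spheroid confocal stack with ground truth, a series of
# brightfield plate images, and two-channel cryosection z-stacks.
# Outputs go to results/data/.

suppressPackageStartupMessages(library(spheroidquant))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## 3D spheroid: 100 cells, rim-high YAP-like N/C gradient (1 at the center,
## 2 at the rim), 30% Ki-67+, mild blur and noise as in a real acquisition.
spec3d <- synthetic_spec_3d(seed = 2024, spheroid_radius_um = 45,
                            n_cells = 100, cell_radius_um_mean = 5.5,
                            cell_radius_um_sd = 0.4,
                            nc_ratio_center = 1, nc_ratio_rim = 2,
                            ki67_fraction = 0.3, background_level = 10,
                            blur_sigma_vox = 0.8, noise_sd = 3)
syn <- generate_spheroid(spec3d)
write_volume(syn$cell_labels, file.path(out, "cell_labels.tif"), syn$spacing)
write_volume(syn$nucleus_labels, file.path(out, "nucleus_labels.tif"), syn$spacing)
write_volume(syn$ki67_labels, file.path(out, "ki67_labels.tif"), syn$spacing)
for (ch in names(syn$channels))
  write_volume(syn$channels[[ch]], file.path(out, paste0("channel_", ch, ".tif")),
               syn$spacing)
write.csv(syn$truth, file.path(out, "truth_3d.csv"), row.names = FALSE)
cat(sprintf("3D spheroid: %d cells, grid %s, %.0f um radius\n",
            nrow(syn$truth), paste(dim(syn$cell_labels), collapse = "x"),
            spec3d$spheroid_radius_um))

## Brightfield series: five wells with varying shape and satellite load
bf_truth <- list()
for (w in 1:5) {
  spec2d <- synthetic_spec_2d(seed = 3000 + w,
                              main_axes_px = c(120 + 15 * w, 100 + 8 * w),
                              angle_deg = 36 * w, n_satellites = 2 * w,
                              noise_sd = 0.02)
  bf <- generate_brightfield(spec2d)
  png::writePNG(bf$image, file.path(out, sprintf("brightfield_well%02d.png", w)))
  bf_truth[[w]] <- data.frame(well = w, diameter_um = bf$truth$diameter_um,
                              eccentricity = bf$truth$eccentricity,
                              loose_area_pct = bf$truth$loose_area_pct)
}
write.csv(do.call(rbind, bf_truth), file.path(out, "truth_brightfield.csv"),
          row.names = FALSE)
cat("brightfield: 5 wells written\n")

## Cryosections: three sections with programmed Involucrin/CK14 ratios
for (k in seq_along(c(0.5, 1, 2))) {
  ratio <- c(0.5, 1, 2)[k]
  cs <- generate_cryosection(seed = 4000 + k, programmed_ratio = ratio,
                             noise_sd = 2)
  write_volume(cs$channel_a, file.path(out, sprintf("cryo%02d_involucrin.tif", k)),
               c(z = 1, y = 0.473, x = 0.473))
  write_volume(cs$channel_b, file.path(out, sprintf("cryo%02d_ck14.tif", k)),
               c(z = 1, y = 0.473, x = 0.473))
}
write.csv(data.frame(section = 1:3, programmed_ratio = c(0.5, 1, 2)),
          file.path(out, "truth_cryosections.csv"), row.names = FALSE)
cat("cryosections: 3 sections written\n")
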