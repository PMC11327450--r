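#!/usr/bin/env Rscript
# Single-spheroid 3D volumetrics from the simulated label volumes: nuclear
# volume filter (300-3000 um3), spheroid-mask reconstruction by 40 closing
# iterations, nuclei density, void region and Ki-67 proliferation index.
# Requires analysis/01_simulate.R to have run.

suppressPackageStartupMessages(library(spheroidquant))

dat <- "results/data"
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

nuclei <- read_volume(file.path(dat, "nucleus_labels.tif"), "labels")
cells <- read_volume(file.path(dat, "cell_labels.tif"), "labels")
ki67 <- read_volume(file.path(dat, "ki67_labels.tif"), "labels")
spacing <- attr(nuclei, "spacing_um")

flt <- filter_nuclei(nuclei, spacing, v_min_um3 = 300, v_max_um3 = 3000)
cat(sprintf("nuclei: %d segmented, %d pass the 300-3000 um3 filter\n",
            nrow(flt$records), sum(flt$records$passes_filter)))
write.csv(flt$records, "results/tables/nuclei_records.csv", row.names = FALSE)

mask <- reconstruct_spheroid_mask(flt$labels, n_iterations = 40)
write_volume(array(as.integer(mask), dim(mask)),
             file.path(dat, "spheroid_mask.tif"), spacing)

dv <- compute_density_and_void(mask, flt$labels, spacing)
ki <- assign_ki67(ki67, cells)
ki_pct <- ki67_fraction(sum(ki), length(ki))

summary_row <- data.frame(
  spheroid_volume_um3 = dv$volume_um3,
  n_nuclei_inside = dv$n_nuclei_inside,
  density_per_1e5_um3 = dv$density_per_1e5_um3,
  void_volume_um3 = dv$void_volume_um3,
  void_fraction = dv$void_volume_um3 / dv$volume_um3,
  ki67_positive_pct = ki_pct)
write.csv(summary_row, "results/tables/volumetrics3d.csv", row.names = FALSE)

cat(sprintf("spheroid volume: %.3g um3 (equivalent sphere radius %.1f um)\n",
            dv$volume_um3, (3 * dv$volume_um3 / (4 * pi))^(1 / 3)))
cat(sprintf("density: %.2f nuclei per 1e5 um3; void fraction: %.1f%%\n",
            dv$density_per_1e5_um3, 100 * summary_row$void_fraction))
cat(sprintf("Ki-67+ fraction: %.1f%%\n", ki_pct))
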