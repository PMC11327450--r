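#!/usr/bin/env Rscript
# One-call orchestration of the whole 3D chain (generator -> volumetrics ->
# N/C ratios -> spatial profile) with a reproducibility manifest, run twice
# to demonstrate end-to-end determinism.

suppressPackageStartupMessages(library(spheroidquant))

cfg <- list(seed = 2024L,
            synthetic = list(spheroid_radius_um = 36, n_cells = 25L))

m1 <- run_all(cfg, out_dir = "results/run_all")
m2 <- run_all(cfg, out_dir = "results/run_all_repeat")

same <- identical(jsonlite::read_json("results/run_all/manifest.json"),
                  jsonlite::read_json("results/run_all_repeat/manifest.json"))
cat(sprintf("manifests identical across repeated runs: %s\n", same))
cat("volumetrics summary:\n")
print(read.csv("results/run_all/volumetrics.csv"), digits = 4,
      row.names = FALSE)
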