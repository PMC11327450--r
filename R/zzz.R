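# data.table non-standard-evaluation column names
utils::globalVariables(c(
  "id", "id_a", "id_b", "overlap", "nvol", "cvol", "score", "frac",
  "v", "m", "n", "y", "x", "z", "cell_id", "nucleus_id",
  "mean_nuc_raw", "mean_cyto_raw", "mean_nuc", "mean_cyto",
  "nuc_vox", "cyto_vox", "nc_ratio", ".SD"
))
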