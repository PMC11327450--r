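# Nucleus-cell matching, cytoplasm derivation, background correction and N/C
# ratios, Ki-67 assignment.

test_that("overlap scoring distinguishes strict IoU from nucleus coverage", {
  # nucleus identical to cell: both metrics score 1
  vol <- array(0L, c(6L, 6L, 6L))
  vol[2:4, 2:4, 2:4] <- 1L
  m_iou <- match_nuclei_to_cells(vol, vol, metric = "iou")
  m_cov <- match_nuclei_to_cells(vol, vol, metric = "nucleus_coverage")
  expect_equal(m_iou$overlap_score, 1)
  expect_equal(m_cov$overlap_score, 1)

  # 8-voxel nucleus inside a 27-voxel cell: iou = 8/27 fails at 0.5,
  # coverage = 1 matches -- the reason the metric is configurable
  cell <- array(0L, c(7L, 7L, 7L))
  cell[2:4, 2:4, 2:4] <- 5L
  nuc <- array(0L, c(7L, 7L, 7L))
  nuc[2:3, 2:3, 2:3] <- 9L
  expect_identical(nrow(match_nuclei_to_cells(nuc, cell, metric = "iou")), 0L)
  m <- match_nuclei_to_cells(nuc, cell, metric = "nucleus_coverage")
  expect_identical(m$cell_id, 5L)
  expect_identical(m$nucleus_id, 9L)
  expect_equal(m$overlap_score, 1)
  m_iou2 <- match_nuclei_to_cells(nuc, cell, threshold = 0.2, metric = "iou")
  expect_equal(m_iou2$overlap_score, 8 / 27)

  expect_error(match_nuclei_to_cells(nuc, cell[1:6, , ]), "grid")
})

test_that("matching equals exhaustive all-pairs scoring with the same tie rules", {
  syn <- fixture_spheroid()
  # decimate to a 2x2x2 coarser grid to keep the oracle cheap, then perturb
  # nuclei by erosion so overlaps are nontrivial
  idx <- list(seq(1, dim(syn$cell_labels)[1], 2),
              seq(1, dim(syn$cell_labels)[2], 2),
              seq(1, dim(syn$cell_labels)[3], 2))
  cell <- syn$cell_labels[idx[[1]], idx[[2]], idx[[3]]]
  nuc <- syn$nucleus_labels[idx[[1]], idx[[2]], idx[[3]]]
  for (metric in c("nucleus_coverage", "iou")) {
    for (thr in c(0.3, 0.5)) {
      got <- match_nuclei_to_cells(nuc, cell, threshold = thr, metric = metric)
      ref <- match_ref(nuc, cell, threshold = thr, metric = metric)
      got <- got[order(got$nucleus_id), ]
      expect_equal(got$nucleus_id, ref$nucleus_id)
      expect_equal(got$cell_id, ref$cell_id)
      expect_equal(got$overlap_score, ref$score)
    }
  }
})

test_that("cytoplasm is the exact set difference of cell and matched nucleus", {
  cell <- array(0L, c(7L, 7L, 7L))
  cell[2:4, 2:4, 2:4] <- 1L
  nuc <- array(0L, c(7L, 7L, 7L))
  nuc[2:3, 2:3, 2:3] <- 1L
  m <- match_nuclei_to_cells(nuc, cell)
  cy <- derive_cytoplasm(cell, nuc, m)
  expect_identical(sum(cy$cytoplasm_labels == 1L), 27L - 8L)
  expect_true(all(cy$cytoplasm_labels[nuc > 0] == 0L))
  expect_length(cy$excluded_cell_ids, 0)

  # nucleus equals cell: empty cytoplasm, cell excluded
  cy2 <- derive_cytoplasm(cell, cell, match_nuclei_to_cells(cell, cell))
  expect_identical(cy2$excluded_cell_ids, 1L)
  expect_true(all(cy2$cytoplasm_labels == 0L))

  # voxel-scan properties on the generated spheroid
  syn <- fixture_spheroid()
  ms <- match_nuclei_to_cells(syn$nucleus_labels, syn$cell_labels)
  cys <- derive_cytoplasm(syn$cell_labels, syn$nucleus_labels, ms)
  cyto <- cys$cytoplasm_labels
  expect_true(all(cyto[syn$nucleus_labels > 0] == 0L))          # disjoint
  in_cell <- syn$cell_labels > 0
  recomposed <- cyto[in_cell] > 0 | syn$nucleus_labels[in_cell] > 0
  expect_true(all(recomposed))                                   # union = cell
  expect_true(all(cyto[in_cell][cyto[in_cell] > 0] ==
                    syn$cell_labels[in_cell][cyto[in_cell] > 0]))
})

test_that("background is the mean outside all detected objects", {
  lab <- array(0L, c(5L, 5L, 4L))
  lab[1:2, 1:2, 1:2] <- 1L
  vol <- array(7, c(5L, 5L, 4L))
  expect_equal(background_level(vol, lab), 7)

  # labels cover all but 10 voxels holding 1..10 -> mean 5.5
  lab2 <- array(1L, c(5L, 5L, 4L))
  lab2[1:10] <- 0L
  vol2 <- array(100, c(5L, 5L, 4L))
  vol2[1:10] <- 1:10
  expect_equal(background_level(vol2, lab2), 5.5)
  expect_equal(background_level(vol2, lab2, fun = "median"), 5.5)
  expect_error(background_level(vol2, array(1L, dim(lab2))), "background")

  syn <- fixture_spheroid()
  expect_equal(background_level(syn$channels$yap, syn$cell_labels),
               mean(syn$channels$yap[syn$cell_labels == 0]))
})

test_that("N/C ratios are background-corrected compartment mean quotients", {
  # forced arithmetic: nuclear 120, cytoplasmic 70, background 20 -> 2.0
  cell <- array(0L, c(7L, 7L, 7L))
  cell[2:5, 2:5, 2:5] <- 1L
  nuc <- array(0L, c(7L, 7L, 7L))
  nuc[3:4, 3:4, 3:4] <- 1L
  vol <- array(20, c(7L, 7L, 7L))
  vol[cell == 1L] <- 70
  vol[nuc == 1L] <- 120
  m <- match_nuclei_to_cells(nuc, cell)
  cy <- derive_cytoplasm(cell, nuc, m)
  bg <- background_level(vol, cell)
  expect_equal(bg, 20)
  r <- compartment_means_and_ratio(vol, nuc, cy$cytoplasm_labels, m, bg,
                                   c(z = 1, y = 1, x = 1))
  expect_equal(r$records$nc_ratio, 2.0)
  expect_equal(r$records$nuc_volume_um3, 8)
  expect_equal(r$records$cyto_volume_um3, 64 - 8)

  # uniform signal: ratio 1 for every cell
  syn <- fixture_spheroid()
  ms <- match_nuclei_to_cells(syn$nucleus_labels, syn$cell_labels)
  cys <- derive_cytoplasm(syn$cell_labels, syn$nucleus_labels, ms)
  flat <- array(42, dim(syn$cell_labels))
  rf <- compartment_means_and_ratio(flat, syn$nucleus_labels,
                                    cys$cytoplasm_labels, ms, 0, syn$spacing)
  expect_true(all(abs(rf$records$nc_ratio - 1) < 1e-12))
})

test_that("programmed constant ratios are recovered exactly without degradation", {
  for (ratio in c(0.5, 1, 2, 4)) {
    spec <- synthetic_spec_3d(seed = 50 + ratio * 10, spheroid_radius_um = 26,
                              n_cells = 8, cell_radius_um_mean = 5,
                              nc_ratio_center = ratio, nc_ratio_rim = ratio,
                              background_level = 10)
    syn <- generate_spheroid(spec)
    m <- match_nuclei_to_cells(syn$nucleus_labels, syn$cell_labels)
    cy <- derive_cytoplasm(syn$cell_labels, syn$nucleus_labels, m)
    bg <- background_level(syn$channels$yap, syn$cell_labels)
    r <- compartment_means_and_ratio(syn$channels$yap, syn$nucleus_labels,
                                     cy$cytoplasm_labels, m, bg, syn$spacing)
    expect_equal(nrow(r$records), 8L)
    expect_true(all(abs(r$records$nc_ratio - ratio) / ratio <= 1e-9))
  }
})

test_that("ratios are invariant to intensity offset and positive gain", {
  syn <- fixture_spheroid()
  m <- match_nuclei_to_cells(syn$nucleus_labels, syn$cell_labels)
  cy <- derive_cytoplasm(syn$cell_labels, syn$nucleus_labels, m)
  run <- function(vol) {
    bg <- background_level(vol, syn$cell_labels)
    compartment_means_and_ratio(vol, syn$nucleus_labels, cy$cytoplasm_labels,
                                m, bg, syn$spacing)$records$nc_ratio
  }
  base <- run(syn$channels$yap)
  expect_equal(run(syn$channels$yap + 55), base, tolerance = 1e-9)  # offset
  expect_equal(run(syn$channels$yap * 3.7), base, tolerance = 1e-9) # gain
  # iou <= nucleus_coverage always
  cov <- match_nuclei_to_cells(syn$nucleus_labels, syn$cell_labels,
                               threshold = 0, metric = "nucleus_coverage")
  iou <- match_nuclei_to_cells(syn$nucleus_labels, syn$cell_labels,
                               threshold = 0, metric = "iou")
  both <- merge(cov, iou, by = c("nucleus_id", "cell_id"))
  expect_true(all(both$overlap_score.y <= both$overlap_score.x + 1e-12))
  expect_true(all(cov$overlap_score >= 0 & cov$overlap_score <= 1))
})

test_that("Ki-67 objects are assigned by majority voxel overlap", {
  cell <- array(0L, c(10L, 10L, 6L))
  cell[1:5, , ] <- 5L
  cell[6:10, , ] <- 7L
  ki <- array(0L, c(10L, 10L, 6L))
  ki[3:4, 3:4, 2:3] <- 1L            # fully inside cell 5
  st <- assign_ki67(ki, cell)
  expect_true(st[["5"]])
  expect_false(st[["7"]])

  # no objects: everything negative
  st0 <- assign_ki67(array(0L, dim(cell)), cell)
  expect_true(all(!st0))

  # straddling object: winner by exhaustive per-cell overlap tally
  ki2 <- array(0L, c(10L, 10L, 6L))
  ki2[4:8, 2:3, 2:3] <- 1L           # rows 4-5 in cell 5 (8 vox), 6-8 in 7 (12)
  st2 <- assign_ki67(ki2, cell)
  ov5 <- sum(ki2 > 0 & cell == 5L)
  ov7 <- sum(ki2 > 0 & cell == 7L)
  expect_identical(st2[["7"]], ov7 / (ov5 + ov7) >= 0.5)
  expect_false(st2[["5"]])

  # below the majority threshold no cell is positive
  st3 <- assign_ki67(ki2, cell, min_object_fraction = 0.7)
  expect_true(all(!st3))
})
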