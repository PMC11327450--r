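# Subcellular N/C ratio chain: nucleus-to-cell matching by overlap, cytoplasm
# derivation by mask subtraction, automatic background correction, per-cell
# compartment means and N/C ratios, and Ki-67 status assignment.

# voxel overlap counts between two label volumes, as a data.table with
# columns id_a, id_b, overlap (voxels where both are > 0)
overlap_table <- function(labels_a, labels_b) {
  idx <- which(labels_a > 0L & labels_b > 0L)
  if (length(idx) == 0L)
    return(data.table(id_a = integer(0), id_b = integer(0), overlap = integer(0)))
  dt <- data.table(id_a = labels_a[idx], id_b = labels_b[idx])
  dt[, .(overlap = .N), keyby = .(id_a, id_b)]
}

#' Match nuclei to whole-cell masks by overlap
#'
#' For every nucleus the candidate cells are those it overlaps. The overlap
#' score is either `nucleus_coverage` (intersection / nucleus volume, the
#' default) or strict `iou` (intersection / union). Candidates scoring at
#' least `threshold` are assigned one-to-one greedily in descending score
#' order (ties: ascending cell id, then ascending nucleus id).
#'
#' Strict IoU between a nucleus and its much larger whole-cell mask rarely
#' reaches 0.5, which would leave everything unmatched; `nucleus_coverage`
#' reads the 50% minimum-overlap rule as the fraction of the nucleus lying
#' inside the cell. Both metrics are available.
#'
#' @param nucleus_labels,cell_labels integer 3D label arrays on one grid.
#' @param threshold minimum accepted score, in [0, 1].
#' @param metric `"nucleus_coverage"` or `"iou"`.
#' @return data.frame with columns `nucleus_id`, `cell_id`, `overlap_score`,
#'   `metric_name`, one row per accepted match.
#' @export
match_nuclei_to_cells <- function(nucleus_labels, cell_labels, threshold = 0.5,
                                  metric = c("nucleus_coverage", "iou")) {
  check_volume(nucleus_labels); check_volume(cell_labels)
  check_same_grid(nucleus_labels, cell_labels)
  metric <- match.arg(metric)
  stopifnot(threshold >= 0, threshold <= 1)
  ov <- overlap_table(nucleus_labels, cell_labels)
  empty <- data.frame(nucleus_id = integer(0), cell_id = integer(0),
                      overlap_score = numeric(0), metric_name = character(0))
  if (nrow(ov) == 0L) return(empty)
  n_vox <- label_counts(nucleus_labels)
  c_vox <- label_counts(cell_labels)
  ov[, nvol := as.numeric(n_vox[as.character(id_a)])]
  ov[, cvol := as.numeric(c_vox[as.character(id_b)])]
  ov[, score := if (metric == "nucleus_coverage") overlap / nvol
     else overlap / (nvol + cvol - overlap)]
  cand <- ov[score >= threshold][order(-score, id_b, id_a)]
  if (nrow(cand) == 0L) return(empty)
  used_n <- integer(0); used_c <- integer(0)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$id_a[i] %in% used_n || cand$id_b[i] %in% used_c) next
    keep[i] <- TRUE
    used_n <- c(used_n, cand$id_a[i])
    used_c <- c(used_c, cand$id_b[i])
  }
  acc <- cand[keep]
  data.frame(nucleus_id = acc$id_a, cell_id = acc$id_b,
             overlap_score = acc$score, metric_name = metric)
}

#' Derive cytoplasm masks by subtracting nuclei from cells
#'
#' For every matched nucleus/cell pair the cytoplasm is the cell's voxels
#' minus the matched nucleus's voxels, labeled with the cell id. Cells whose
#' cytoplasm comes out empty are reported in `excluded_cell_ids`; unmatched
#' cells are not part of the output.
#'
#' @inheritParams match_nuclei_to_cells
#' @param matches data.frame from [match_nuclei_to_cells()].
#' @return list with `cytoplasm_labels` (integer 3D array) and
#'   `excluded_cell_ids`.
#' @export
derive_cytoplasm <- function(cell_labels, nucleus_labels, matches) {
  check_volume(cell_labels); check_volume(nucleus_labels)
  check_same_grid(cell_labels, nucleus_labels)
  stopifnot(all(c("nucleus_id", "cell_id") %in% names(matches)))
  cyto <- array(0L, dim(cell_labels))
  if (nrow(matches) == 0L)
    return(list(cytoplasm_labels = cyto, excluded_cell_ids = integer(0)))
  max_id <- max(c(0L, cell_labels))
  keep_cell <- logical(max_id + 1L)          # index by cell id + 1
  keep_cell[matches$cell_id + 1L] <- TRUE
  nuc_of_cell <- integer(max_id + 1L)        # matched nucleus id per cell id
  nuc_of_cell[matches$cell_id + 1L] <- matches$nucleus_id

  in_cell <- cell_labels > 0L & keep_cell[cell_labels + 1L]
  # voxel is cytoplasm unless it belongs to the matched nucleus of that cell
  is_nuc <- in_cell & nucleus_labels > 0L &
    nucleus_labels == nuc_of_cell[cell_labels + 1L]
  sel <- in_cell & !is_nuc
  cyto[sel] <- cell_labels[sel]
  present <- label_counts(cyto)
  excluded <- setdiff(matches$cell_id, as.integer(names(present)))
  list(cytoplasm_labels = cyto, excluded_cell_ids = sort(excluded))
}

#' Automatic background level of an intensity volume
#'
#' The background is the mean intensity over all voxels outside the detected
#' objects (cell label 0).
#'
#' @param intensity numeric 3D array.
#' @param cell_labels integer 3D label array on the same grid.
#' @param fun summary statistic, `"mean"` (default) or `"median"`.
#' @return scalar background level (a.u.).
#' @export
background_level <- function(intensity, cell_labels, fun = c("mean", "median")) {
  check_volume(intensity); check_volume(cell_labels)
  check_same_grid(intensity, cell_labels)
  fun <- match.arg(fun)
  bg <- intensity[cell_labels == 0L]
  if (length(bg) == 0L) stop("no background voxels (labels cover the volume)",
                             call. = FALSE)
  if (fun == "mean") mean(bg) else stats::median(bg)
}

#' Background-corrected compartment means and N/C ratios
#'
#' Per matched cell, the nuclear and cytoplasmic means are the sum of voxel
#' intensities divided by the compartment voxel count; the background is
#' subtracted from both, and the N/C ratio is their quotient. Cells with an
#' empty cytoplasm or a corrected cytoplasmic mean <= 0 are excluded from the
#' ratio table and tallied in the QC counts.
#'
#' @param intensity numeric 3D array (e.g. the YAP channel).
#' @param nucleus_labels integer 3D nucleus label array.
#' @param cytoplasm_labels integer 3D cytoplasm label array carrying cell ids
#'   (from [derive_cytoplasm()]).
#' @param matches data.frame from [match_nuclei_to_cells()].
#' @param background scalar from [background_level()].
#' @param spacing voxel spacing in micrometres.
#' @param ki67_status optional logical vector named by cell id.
#' @return list with `records` (data.frame: `cell_id`, `mean_nuc`,
#'   `mean_cyto`, `background`, `nc_ratio`, `ki67_status`, `nuc_volume_um3`,
#'   `cyto_volume_um3`) and `qc` (list: `n_input`, `n_excluded_empty_cyto`,
#'   `n_excluded_nonpositive_cyto`).
#' @export
compartment_means_and_ratio <- function(intensity, nucleus_labels,
                                        cytoplasm_labels, matches, background,
                                        spacing, ki67_status = NULL) {
  check_volume(intensity)
  check_same_grid(intensity, nucleus_labels)
  check_same_grid(intensity, cytoplasm_labels)
  spacing <- normalize_spacing(spacing)
  vv <- voxel_volume_um3(spacing)

  mean_by_label <- function(labels) {
    idx <- which(labels > 0L)
    if (length(idx) == 0L)
      return(data.table(id = integer(0), m = numeric(0), n = integer(0)))
    dt <- data.table(id = labels[idx], v = intensity[idx])
    dt[, .(m = mean(v), n = .N), keyby = id]
  }
  nuc <- mean_by_label(nucleus_labels)
  cyt <- mean_by_label(cytoplasm_labels)

  rec <- data.table(cell_id = matches$cell_id, nucleus_id = matches$nucleus_id)
  rec[, mean_nuc_raw := nuc$m[match(nucleus_id, nuc$id)]]
  rec[, nuc_vox := nuc$n[match(nucleus_id, nuc$id)]]
  rec[, mean_cyto_raw := cyt$m[match(cell_id, cyt$id)]]
  rec[, cyto_vox := cyt$n[match(cell_id, cyt$id)]]

  n_empty <- sum(is.na(rec$mean_cyto_raw))
  rec <- rec[!is.na(mean_cyto_raw)]
  rec[, mean_nuc := mean_nuc_raw - background]
  rec[, mean_cyto := mean_cyto_raw - background]
  n_nonpos <- sum(rec$mean_cyto <= 0)
  rec <- rec[mean_cyto > 0]
  rec[, nc_ratio := mean_nuc / mean_cyto]

  ki <- rep(NA, nrow(rec))
  if (!is.null(ki67_status))
    ki <- as.logical(ki67_status[as.character(rec$cell_id)])
  records <- data.frame(cell_id = rec$cell_id, mean_nuc = rec$mean_nuc,
                        mean_cyto = rec$mean_cyto, background = background,
                        nc_ratio = rec$nc_ratio, ki67_status = ki,
                        nuc_volume_um3 = rec$nuc_vox * vv,
                        cyto_volume_um3 = rec$cyto_vox * vv)
  records <- records[order(records$cell_id), , drop = FALSE]
  rownames(records) <- NULL
  list(records = records,
       qc = list(n_input = nrow(matches),
                 n_excluded_empty_cyto = n_empty,
                 n_excluded_nonpositive_cyto = n_nonpos))
}

#' Assign Ki-67 status to cells
#'
#' Each Ki-67 object is assigned to the cell containing the largest fraction
#' of its voxels, provided that fraction is at least `min_object_fraction`
#' (ties: ascending cell id). A cell is Ki-67 positive when at least one
#' object is assigned to it.
#'
#' @param ki67_labels,cell_labels integer 3D label arrays on one grid.
#' @param min_object_fraction minimum fraction of the object's voxels that
#'   must lie inside the winning cell.
#' @return logical vector named by cell id (every id present in
#'   `cell_labels`), TRUE for Ki-67 positive.
#' @export
assign_ki67 <- function(ki67_labels, cell_labels, min_object_fraction = 0.5) {
  check_volume(ki67_labels); check_volume(cell_labels)
  check_same_grid(ki67_labels, cell_labels)
  cell_ids <- as.integer(names(label_counts(cell_labels)))
  status <- stats::setNames(rep(FALSE, length(cell_ids)), cell_ids)
  obj_vox <- label_counts(ki67_labels)
  if (length(obj_vox) == 0L) return(status)
  ov <- overlap_table(ki67_labels, cell_labels)
  if (nrow(ov) == 0L) return(status)
  ov[, frac := overlap / as.numeric(obj_vox[as.character(id_a)])]
  best <- ov[order(id_a, -frac, id_b), .SD[1], keyby = id_a]
  pos_cells <- unique(best[frac >= min_object_fraction]$id_b)
  status[as.character(pos_cells[pos_cells %in% cell_ids])] <- TRUE
  status
}
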