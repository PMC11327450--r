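# Independent oracle implementations and shared fixtures. The oracles are
# deliberately naive (literal shifts, exhaustive scans) so they share no code
# path with the package implementation.

# ---- literal shift-based binary morphology (reference implementation) ------

shift_logical <- function(m, ax, by) {
  dm <- dim(m)
  out <- array(FALSE, dm)
  src <- dst <- lapply(dm, seq_len)
  if (by == 1) {
    dst[[ax]] <- 2:dm[ax]; src[[ax]] <- 1:(dm[ax] - 1)
  } else {
    dst[[ax]] <- 1:(dm[ax] - 1); src[[ax]] <- 2:dm[ax]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    m[src[[1]], src[[2]], src[[3]]]
  out
}

dilate_ref <- function(m, k) {
  for (i in seq_len(k))
    m <- m |
      shift_logical(m, 1, 1) | shift_logical(m, 1, -1) |
      shift_logical(m, 2, 1) | shift_logical(m, 2, -1) |
      shift_logical(m, 3, 1) | shift_logical(m, 3, -1)
  m
}

erode_ref <- function(m, k) {
  # literal zero-padded erosion: out-of-volume counts as background
  for (i in seq_len(k))
    m <- m &
      shift_logical(m, 1, 1) & shift_logical(m, 1, -1) &
      shift_logical(m, 2, 1) & shift_logical(m, 2, -1) &
      shift_logical(m, 3, 1) & shift_logical(m, 3, -1)
  m
}

# ---- exhaustive all-pairs nucleus/cell matcher -----------------------------

match_ref <- function(nuc, cell, threshold = 0.5,
                      metric = c("nucleus_coverage", "iou")) {
  metric <- match.arg(metric)
  nids <- sort(unique(nuc[nuc > 0]))
  rows <- list()
  for (ni in nids) {
    nmask <- nuc == ni
    cands <- setdiff(sort(unique(cell[nmask])), 0)  # zero-overlap pairs score 0
    for (ci in cands) {
      cmask <- cell == ci
      inter <- sum(nmask & cmask)
      s <- if (metric == "nucleus_coverage") inter / sum(nmask)
           else inter / sum(nmask | cmask)
      rows[[length(rows) + 1]] <- data.frame(nucleus_id = ni, cell_id = ci,
                                             score = s)
    }
  }
  if (length(rows) == 0)
    return(data.frame(nucleus_id = integer(0), cell_id = integer(0),
                      score = numeric(0)))
  cand <- do.call(rbind, rows)
  cand <- cand[cand$score >= threshold, , drop = FALSE]
  cand <- cand[order(-cand$score, cand$cell_id, cand$nucleus_id), , drop = FALSE]
  used_n <- used_c <- integer(0)
  out <- list()
  for (i in seq_len(nrow(cand))) {
    if (cand$nucleus_id[i] %in% used_n || cand$cell_id[i] %in% used_c) next
    out[[length(out) + 1]] <- cand[i, ]
    used_n <- c(used_n, cand$nucleus_id[i])
    used_c <- c(used_c, cand$cell_id[i])
  }
  if (length(out) == 0)
    return(data.frame(nucleus_id = integer(0), cell_id = integer(0),
                      score = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$nucleus_id), , drop = FALSE]
}

# ---- small fixture volumes --------------------------------------------------

# place an axis-aligned ellipsoid (physical radii, um) into an integer array
paint_ellipsoid <- function(lab, id, center_um, radii_um, spacing) {
  dm <- dim(lab)
  sp <- spheroidquant::normalize_spacing(spacing)
  ax <- list((seq_len(dm[1]) - 0.5) * sp[["y"]],
             (seq_len(dm[2]) - 0.5) * sp[["x"]],
             (seq_len(dm[3]) - 0.5) * sp[["z"]])
  d2 <- outer(outer(((ax[[1]] - center_um[1]) / radii_um[1])^2,
                    ((ax[[2]] - center_um[2]) / radii_um[2])^2, `+`),
              ((ax[[3]] - center_um[3]) / radii_um[3])^2, `+`)
  lab[d2 <= 1] <- id
  lab
}

# cached synthetic spheroid shared across test files (expensive to generate)
.fixture_env <- new.env(parent = emptyenv())

fixture_spheroid <- function() {
  if (is.null(.fixture_env$syn)) {
    spec <- spheroidquant::synthetic_spec_3d(
      seed = 101, spheroid_radius_um = 36, n_cells = 25,
      cell_radius_um_mean = 6.5, cell_radius_um_sd = 0.5,
      nc_ratio_center = 1, nc_ratio_rim = 2, background_level = 10)
    .fixture_env$syn <- spheroidquant::generate_spheroid(spec)
  }
  .fixture_env$syn
}

# 128^3 densely packed nuclei cluster for closing equivalence tests
fixture_packed_128 <- function() {
  if (is.null(.fixture_env$packed)) {
    set.seed(41)
    dm <- c(128L, 128L, 128L)
    lab <- array(0L, dm)
    ctr <- c(64, 64, 64)
    centers <- NULL
    n <- 0
    while (n < 60) {
      p <- stats::runif(3, -17, 17)
      if (sum(p^2) > 17^2) next
      if (!is.null(centers) && any(colSums((t(centers) - p)^2) < 36)) next
      centers <- rbind(centers, p)
      n <- n + 1
    }
    for (i in seq_len(nrow(centers)))
      lab <- paint_ellipsoid(lab, i, centers[i, ] + ctr,
                             c(2.8, 2.8, 2.8), c(1, 1, 1))
    .fixture_env$packed <- lab
  }
  .fixture_env$packed
}
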