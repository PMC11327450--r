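# Spatial distance-to-rim profiling: convex hull around cell centroids,
# hull-center ray intersection distances, and radial binning of N/C ratio and
# Ki-67 status.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Convex hull of 3D points
#'
#' Incremental (quickhull-style) construction: starting from an extreme
#' tetrahedron, each remaining point outside the current hull removes its
#' visible faces and is stitched to the horizon edges. Faces are oriented
#' with outward normals. The hull center is the volume centroid of the
#' polyhedron (the mean of input points is available in `point_mean`).
#'
#' @param centroids numeric matrix, one point per row, 3 columns
#'   (micrometres; any consistent axis order).
#' @param tol numeric tolerance for coplanarity/visibility tests, scaled by
#'   the data extent.
#' @return list of class `hull_model`: `vertices` (matrix of hull vertex
#'   coordinates), `faces` (integer matrix, 3 columns, indices into
#'   `vertices`), `center` (volume centroid), `point_mean`.
#' @export
build_hull <- function(centroids, tol = 1e-10) {
  stopifnot(is.matrix(centroids) || is.data.frame(centroids))
  pts <- as.matrix(centroids)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3L) stop("centroids must have 3 columns", call. = FALSE)
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 4L) stop("need >= 4 distinct points for a 3D hull", call. = FALSE)
  scale <- max(apply(pts, 2, function(c) diff(range(c))))
  if (scale == 0) stop("degenerate input: all points coincide", call. = FALSE)
  eps <- tol + 1e-9 * scale

  # initial tetrahedron from extreme points
  i1 <- which.min(pts[, 1])
  d1 <- colSums((t(pts) - pts[i1, ])^2)
  i2 <- which.max(d1)
  e12 <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2, pts[i1, ])
  crossn <- t(apply(rel, 1, function(r) cross3(e12, r)))
  i3 <- which.max(rowSums(crossn^2))
  nrm <- cross3(e12, pts[i3, ] - pts[i1, ])
  if (sum(nrm^2) <= (eps * scale)^2)
    stop("degenerate input: points are collinear", call. = FALSE)
  h <- abs(rel %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(h)
  if (h[i4] <= eps)
    stop("degenerate input: points are coplanar", call. = FALSE)

  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  tet_center <- colMeans(pts[c(i1, i2, i3, i4), ])
  orient_out <- function(f) {
    nn <- cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    if (sum(nn * (tet_center - pts[f[1], ])) > 0) f[c(1, 3, 2)] else f
  }
  faces <- t(apply(faces, 1, orient_out))

  face_normal <- function(f) {
    nn <- cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    nn / sqrt(sum(nn^2))
  }
  normals <- t(apply(faces, 1, face_normal))
  offsets <- rowSums(normals * pts[faces[, 1], , drop = FALSE])

  for (p in setdiff(seq_len(n), c(i1, i2, i3, i4))) {
    vis <- (normals %*% pts[p, ]) - offsets > eps
    if (!any(vis)) next
    vis_faces <- faces[vis, , drop = FALSE]
    # horizon = directed edges of visible faces whose reverse is not visible
    edges <- rbind(vis_faces[, c(1, 2)], vis_faces[, c(2, 3)], vis_faces[, c(3, 1)])
    keys <- paste(edges[, 1], edges[, 2])
    rev_keys <- paste(edges[, 2], edges[, 1])
    horizon <- edges[!(keys %in% rev_keys), , drop = FALSE]
    new_faces <- cbind(horizon, p)
    faces <- rbind(faces[!vis, , drop = FALSE], new_faces)
    new_normals <- t(apply(new_faces, 1, face_normal))
    normals <- rbind(normals[!vis, , drop = FALSE], new_normals)
    offsets <- c(offsets[!vis],
                 rowSums(new_normals * pts[new_faces[, 1], , drop = FALSE]))
  }

  vert_idx <- sort(unique(as.vector(faces)))
  remap <- integer(n); remap[vert_idx] <- seq_along(vert_idx)
  vertices <- pts[vert_idx, , drop = FALSE]
  faces2 <- matrix(remap[faces], ncol = 3)

  # volume centroid: signed tetrahedra against the vertex mean
  ref <- colMeans(vertices)
  v6 <- 0; cen <- c(0, 0, 0)
  for (k in seq_len(nrow(faces2))) {
    a <- vertices[faces2[k, 1], ] - ref
    b <- vertices[faces2[k, 2], ] - ref
    cc <- vertices[faces2[k, 3], ] - ref
    sv <- sum(a * cross3(b, cc))
    v6 <- v6 + sv
    cen <- cen + sv * (a + b + cc) / 4
  }
  center <- ref + cen / v6

  structure(list(vertices = vertices, faces = faces2, center = center,
                 point_mean = colMeans(pts), volume_um3 = abs(v6) / 6),
            class = "hull_model")
}

#' Distance from a cell centroid to the hull surface along the center ray
#'
#' Casts the ray from the hull center through the centroid, intersects it with
#' the triangulated hull surface (nearest forward ray-triangle hit; ties
#' resolved by smallest face index) and returns the Euclidean distance from
#' the intersection point to the centroid. Centroids that fall outside the
#' hull by floating error are clamped to distance 0. A centroid coincident
#' with the center has no ray direction; the minimum center-to-face distance
#' is returned with a warning.
#'
#' @param hull a `hull_model` from [build_hull()].
#' @param centroid numeric length-3 point, or a matrix of points (one per
#'   row).
#' @return numeric distance(s) in the input units.
#' @export
distance_to_hull <- function(hull, centroid) {
  stopifnot(inherits(hull, "hull_model"))
  if (is.matrix(centroid) || is.data.frame(centroid)) {
    m <- as.matrix(centroid)
    return(vapply(seq_len(nrow(m)), function(i) distance_to_hull(hull, m[i, ]),
                  numeric(1)))
  }
  p <- as.numeric(centroid)
  stopifnot(length(p) == 3L)
  ctr <- hull$center
  dir <- p - ctr
  dl <- sqrt(sum(dir^2))
  scale <- max(abs(hull$vertices - matrix(ctr, nrow(hull$vertices), 3, byrow = TRUE)))
  if (dl < 1e-12 * max(scale, 1)) {
    warning("centroid coincides with the hull center; returning the minimum center-to-face distance",
            call. = FALSE)
    v <- hull$vertices; f <- hull$faces
    dmin <- Inf
    for (k in seq_len(nrow(f))) {
      nn <- cross3(v[f[k, 2], ] - v[f[k, 1], ], v[f[k, 3], ] - v[f[k, 1], ])
      nn <- nn / sqrt(sum(nn^2))
      dmin <- min(dmin, abs(sum(nn * (ctr - v[f[k, 1], ]))))
    }
    return(dmin)
  }
  dir <- dir / dl

  # Moller-Trumbore over all faces, vectorized
  v <- hull$vertices; f <- hull$faces
  v0 <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - v0
  e2 <- v[f[, 3], , drop = FALSE] - v0
  pv <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
              dir[3] * e2[, 1] - dir[1] * e2[, 3],
              dir[1] * e2[, 2] - dir[2] * e2[, 1])
  det <- rowSums(e1 * pv)
  tvec <- matrix(ctr, nrow(v0), 3, byrow = TRUE) - v0
  u <- rowSums(tvec * pv) / det
  qv <- cbind(tvec[, 2] * e1[, 3] - tvec[, 3] * e1[, 2],
              tvec[, 3] * e1[, 1] - tvec[, 1] * e1[, 3],
              tvec[, 1] * e1[, 2] - tvec[, 2] * e1[, 1])
  vv <- as.numeric(qv %*% dir) / det
  tt <- rowSums(e2 * qv) / det
  geps <- 1e-9
  ok <- is.finite(tt) & abs(det) > .Machine$double.eps &
    u >= -geps & vv >= -geps & (u + vv) <= 1 + geps & tt > 0
  if (!any(ok)) return(0)  # numerically outside the hull: clamp
  t_hit <- min(tt[ok])     # smallest forward hit = the surface crossing
  max(0, t_hit - dl)
}

#' Join per-cell measurements into spatial records
#'
#' Builds the hull over all centroids and computes each cell's
#' distance-to-hull, carrying N/C ratio and Ki-67 status along.
#'
#' @param records data.frame from [compartment_means_and_ratio()] (needs
#'   `cell_id`, `nc_ratio`, `ki67_status`).
#' @param centroids numeric matrix of centroids in micrometres, rows named by
#'   cell id (e.g. from [filter_nuclei()] records or generator truth).
#' @return list with `records` (data.frame adding `distance_to_hull_um` and
#'   centroid columns) and `hull` (the `hull_model`).
#' @export
spatial_records <- function(records, centroids) {
  stopifnot(all(c("cell_id", "nc_ratio") %in% names(records)))
  m <- as.matrix(centroids)
  if (is.null(rownames(m))) stop("centroids must have row names = cell ids",
                                 call. = FALSE)
  hull <- build_hull(m)
  sel <- m[as.character(records$cell_id), , drop = FALSE]
  d <- distance_to_hull(hull, sel)
  out <- records
  out$centroid_y_um <- sel[, 1]
  out$centroid_x_um <- sel[, 2]
  out$centroid_z_um <- sel[, 3]
  out$distance_to_hull_um <- d
  list(records = out, hull = hull)
}

#' Radial profile of N/C ratio and Ki-67 fraction
#'
#' Bins cells into `n_bins` equal-width distance-to-hull bins over
#' `[0, max(distance)]` and aggregates per bin. Empty bins are reported with
#' `n = 0` and NA aggregates.
#'
#' @param records data.frame with `distance_to_hull_um`, `nc_ratio` and
#'   optionally `ki67_status`.
#' @param n_bins number of bins (>= 1).
#' @return data.frame: `bin`, `bin_center_um`, `bin_lo_um`, `bin_hi_um`, `n`,
#'   `mean_nc_ratio`, `median_nc_ratio`, `ki67_pos_fraction`.
#' @export
radial_profile <- function(records, n_bins = 10) {
  stopifnot(nrow(records) >= 1L)
  if (n_bins < 1) stop("n_bins must be >= 1", call. = FALSE)
  d <- records$distance_to_hull_um
  hi <- max(d)
  breaks <- seq(0, max(hi, .Machine$double.eps), length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(d, breaks, rightmost.closed = TRUE), 1L), n_bins)
  out <- data.frame(bin = seq_len(n_bins),
                    bin_lo_um = breaks[-length(breaks)],
                    bin_hi_um = breaks[-1])
  out$bin_center_um <- (out$bin_lo_um + out$bin_hi_um) / 2
  agg <- function(f) vapply(seq_len(n_bins), function(b) {
    v <- records[bin == b, , drop = FALSE]
    if (nrow(v) == 0L) NA_real_ else f(v)
  }, numeric(1))
  out$n <- vapply(seq_len(n_bins), function(b) sum(bin == b), integer(1))
  out$mean_nc_ratio <- agg(function(v) mean(v$nc_ratio))
  out$median_nc_ratio <- agg(function(v) stats::median(v$nc_ratio))
  out$ki67_pos_fraction <- if ("ki67_status" %in% names(records))
    agg(function(v) mean(as.logical(v$ki67_status))) else NA_real_
  out[, c("bin", "bin_center_um", "bin_lo_um", "bin_hi_um", "n",
          "mean_nc_ratio", "median_nc_ratio", "ki67_pos_fraction")]
}
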