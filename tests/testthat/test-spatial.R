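# Convex hull construction, ray-intersection distance to the hull surface,
# and radial profiling.

cube_pts <- as.matrix(expand.grid(y = c(-1, 1), x = c(-1, 1), z = c(-1, 1)))

test_that("hull of cube corners is the cube; interior points are ignored", {
  h <- build_hull(cube_pts)
  expect_identical(nrow(h$vertices), 8L)
  expect_equal(unname(h$center), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(h$volume_um3, 8)

  set.seed(12)
  inner <- matrix(stats::runif(90, -0.9, 0.9), ncol = 3)
  h2 <- build_hull(rbind(cube_pts, inner))
  expect_identical(nrow(h2$vertices), 8L)
  expect_equal(sort(apply(h2$vertices, 1, paste, collapse = ",")),
               sort(apply(h$vertices, 1, paste, collapse = ",")))

  expect_error(build_hull(cube_pts[1:3, ]), ">= 4")
  flat <- cbind(matrix(stats::runif(40), ncol = 2), 0)
  expect_error(build_hull(flat), "coplanar")
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(build_hull(line), "collinear|coplanar")
})

test_that("every input point lies inside or on the hull (half-space oracle)", {
  set.seed(13)
  pts <- matrix(stats::rnorm(1500), ncol = 3)
  h <- build_hull(pts)
  # oracle: sign test of every point against every face plane
  for (k in seq_len(nrow(h$faces))) {
    a <- h$vertices[h$faces[k, 1], ]
    b <- h$vertices[h$faces[k, 2], ]
    cc <- h$vertices[h$faces[k, 3], ]
    nrm <- c((b - a)[2] * (cc - a)[3] - (b - a)[3] * (cc - a)[2],
             (b - a)[3] * (cc - a)[1] - (b - a)[1] * (cc - a)[3],
             (b - a)[1] * (cc - a)[2] - (b - a)[2] * (cc - a)[1])
    s <- (pts %*% nrm) - sum(nrm * a)
    expect_true(all(s <= 1e-9 * max(abs(pts))))
  }
})

test_that("distance to hull matches analytic values on the cube", {
  h <- build_hull(cube_pts)
  # centroid on a hull vertex: distance 0
  expect_equal(distance_to_hull(h, c(1, 1, 1)), 0, tolerance = 1e-9)
  # interior point on an axis: exits at the face center
  expect_equal(distance_to_hull(h, c(0.5, 0, 0)), 0.5, tolerance = 1e-12)
  expect_equal(distance_to_hull(h, c(0, -0.25, 0)), 0.75, tolerance = 1e-12)
  # center itself: direction undefined, minimum center-to-face distance
  expect_warning(d0 <- distance_to_hull(h, c(0, 0, 0)), "center")
  expect_equal(d0, 1)
})

test_that("spherical shells give distance ~ R - r within 2% of R", {
  set.seed(5)
  R <- 50
  u <- matrix(stats::rnorm(1500), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * R
  h <- build_hull(u)
  dirs <- matrix(stats::rnorm(60), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  for (r in c(5, 15, 25, 35, 45)) {
    d <- distance_to_hull(h, dirs * r)
    expect_true(all(abs(d - (R - r)) <= 0.02 * R))
  }
})

test_that("distances are invariant under rigid transforms", {
  set.seed(14)
  pts <- matrix(stats::rnorm(600, sd = 20), ncol = 3)
  probe <- pts[1:40, ] * 0.6
  h <- build_hull(pts)
  d0 <- distance_to_hull(h, probe)

  th <- 0.7; ph <- 0.3
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Rx <- rbind(c(1, 0, 0), c(0, cos(ph), -sin(ph)), c(0, sin(ph), cos(ph)))
  Q <- Rz %*% Rx
  shift <- c(11, -7, 3)
  pts2 <- sweep(pts %*% t(Q), 2, shift, `+`)
  probe2 <- sweep(probe %*% t(Q), 2, shift, `+`)
  d1 <- distance_to_hull(build_hull(pts2), probe2)
  expect_equal(d1, d0, tolerance = 1e-6 * 20)

  # boundary consistency: no distance exceeds the maximal pairwise extent
  expect_lte(max(d0), max(stats::dist(pts)))
})

test_that("radial profile bins and aggregates match manual assignment", {
  rec <- data.frame(cell_id = 1:10,
                    distance_to_hull_um = c(0, 1, 2, 3, 4, 5, 6, 7, 8, 10),
                    nc_ratio = seq(2, 0.2, length.out = 10),
                    ki67_status = rep(c(TRUE, FALSE), 5))
  prof <- radial_profile(rec, n_bins = 2)
  expect_identical(prof$n, c(5L, 5L))                 # [0,5) and [5,10]
  expect_equal(prof$mean_nc_ratio[1], mean(rec$nc_ratio[rec$distance_to_hull_um < 5]))
  expect_equal(prof$ki67_pos_fraction[2],
               mean(rec$ki67_status[rec$distance_to_hull_um >= 5]))

  # all cells at one distance: everything in a single bin
  rec1 <- data.frame(cell_id = 1:4, distance_to_hull_um = rep(3, 4),
                     nc_ratio = 1:4)
  prof1 <- radial_profile(rec1, n_bins = 3)
  expect_identical(sum(prof1$n), 4L)
  expect_identical(sum(prof1$n > 0), 1L)

  expect_error(radial_profile(rec, n_bins = 0), "n_bins")
})

test_that("programmed rim-high gradient produces a monotone radial profile", {
  syn <- fixture_spheroid()   # nc_ratio_center = 1, nc_ratio_rim = 2
  # bin the exact programmed ratios by true distance-to-rim: binning and
  # aggregation must reproduce the monotone gradient
  rec <- data.frame(cell_id = syn$truth$id,
                    distance_to_hull_um = syn$truth$true_distance_to_rim_um,
                    nc_ratio = syn$truth$true_nc_ratio)
  prof <- radial_profile(rec, n_bins = 5)
  m <- prof$mean_nc_ratio[prof$n > 0]
  expect_true(all(diff(m) < 0))   # ratio falls with depth

  # hull-based records: rank correlation is strongly negative
  m2 <- match_nuclei_to_cells(syn$nucleus_labels, syn$cell_labels)
  cy <- derive_cytoplasm(syn$cell_labels, syn$nucleus_labels, m2)
  bg <- background_level(syn$channels$yap, syn$cell_labels)
  cm <- compartment_means_and_ratio(syn$channels$yap, syn$nucleus_labels,
                                    cy$cytoplasm_labels, m2, bg, syn$spacing)
  cen <- label_centroids_um(syn$nucleus_labels, syn$spacing)
  sr <- spatial_records(cm$records, cen)
  rho <- stats::cor(sr$records$nc_ratio, sr$records$distance_to_hull_um,
                    method = "spearman")
  expect_lt(rho, -0.5)
})
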