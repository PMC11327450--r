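# Brightfield morphometry: segmentation, diameter/eccentricity, loose-cell
# area fraction.

disk_image <- function(nr, nc, cy, cx, r, bg = 0.9, fg = 0.2) {
  yy <- matrix(seq_len(nr) - 0.5, nr, nc)
  xx <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)
  img <- matrix(bg, nr, nc)
  img[(yy - cy)^2 + (xx - cx)^2 <= r^2] <- fg
  img
}

test_that("main-spheroid segmentation recovers a clean disk pixel-exactly", {
  img <- disk_image(120, 120, 60, 60, 30)
  mask <- segment_main_spheroid(img)
  expect_identical(mask, img == 0.2)

  # a 10x smaller satellite is rejected by the largest-component rule
  img2 <- img
  img2[(row(img2) - 15)^2 + (col(img2) - 15)^2 <= 3^2] <- 0.2
  mask2 <- segment_main_spheroid(img2)
  expect_identical(mask2, img == 0.2)

  expect_error(segment_main_spheroid(matrix(1, 10, 10) -
                                       matrix(1, 10, 10)), "foreground")
})

test_that("noisy synthetic ellipse is segmented to within 2% of the true area", {
  bf <- generate_brightfield(synthetic_spec_2d(seed = 21, noise_sd = 0.03,
                                               n_satellites = 0))
  mask <- segment_main_spheroid(bf$image)
  expect_lt(abs(sum(mask) - bf$truth$main_area_px) / bf$truth$main_area_px, 0.02)
})

test_that("diameter is the equivalent-circle diameter and scales with pixel size", {
  img <- disk_image(140, 140, 70, 70, 50)
  mask <- segment_main_spheroid(img)
  m <- measure_diameter_eccentricity(mask, 1)
  expect_equal(m$diameter_um, 100, tolerance = 0.01)   # +-1 px discretization
  expect_lte(m$eccentricity, 0.05)

  # scale covariance is exact: doubling pixel size doubles the diameter
  m2 <- measure_diameter_eccentricity(mask, 2)
  expect_identical(m2$diameter_um, 2 * m$diameter_um)
  expect_identical(m2$area_um2, 4 * m$area_um2)

  # diameter equals the brute-force pixel-count formula on an arbitrary blob
  set.seed(8)
  blob <- matrix(stats::runif(80 * 80) < 0.4, 80, 80)
  mm <- measure_diameter_eccentricity(blob, 0.65)
  expect_equal(mm$diameter_um, 2 * sqrt(sum(blob) / pi) * 0.65)

  expect_error(measure_diameter_eccentricity(matrix(FALSE, 5, 5), 1), "empty")
})

test_that("eccentricity matches the analytic ellipse value and is rotation-stable", {
  eccs <- sapply(c(0, 30, 45, 70), function(ang) {
    bf <- generate_brightfield(synthetic_spec_2d(seed = 3,
      main_axes_px = c(160, 80), angle_deg = ang, n_satellites = 0,
      noise_sd = 0))
    measure_diameter_eccentricity(segment_main_spheroid(bf$image),
                                  bf$pixel_size_um)$eccentricity
  })
  expect_true(all(abs(eccs - sqrt(1 - 1 / 4)) < 0.01))
  expect_lt(max(eccs) - min(eccs), 0.02)
})

test_that("loose-cell percentage is exact forced arithmetic on clean input", {
  # blank surround: 0%
  img <- disk_image(100, 100, 50, 50, 20)
  mask <- segment_main_spheroid(img)
  r0 <- measure_loose_cell_area(img, mask, gaussian_sigma_px = 0)
  expect_equal(r0$occupied_area_fraction, 0)
  expect_identical(r0$n_objects, 0L)

  # satellites covering exactly 400 px of a 100x100 image: 4.0%
  img4 <- img
  img4[5:24, 5:24] <- 0.2                 # 400-pixel square satellite
  r4 <- measure_loose_cell_area(img4, mask, gaussian_sigma_px = 0)
  expect_equal(r4$occupied_area_fraction, 4.0)
  expect_identical(r4$n_objects, 1L)
  expect_equal(r4$object_areas_px, 400)

  expect_error(measure_loose_cell_area(img, mask,
                                       diameter_band_px = c(200, 5)),
               "inverted")
})

test_that("the diameter band filter equals an exhaustive per-object scan", {
  # objects straddling the 5-200 px equivalent-diameter band
  img <- matrix(0.9, 300, 300)
  img[100:220, 100:220] <- 0.2                         # main object
  squares <- list(c(5, 5, 2), c(20, 20, 5), c(40, 60, 12), c(150, 5, 40),
                  c(200, 250, 3), c(230, 10, 60))
  for (s in squares)
    img[s[1]:(s[1] + s[3] - 1), s[2]:(s[2] + s[3] - 1)] <- 0.2
  main <- segment_main_spheroid(img)
  res <- measure_loose_cell_area(img, main, gaussian_sigma_px = 0,
                                 diameter_band_px = c(5, 60))

  # oracle: scan every labeled object, apply the band to equivalent diameters
  fg <- img < 0.5
  lab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(fg))), 300, 300)
  kept_oracle <- 0L
  ids <- setdiff(unique(lab[lab > 0]), unique(lab[main]))
  areas <- c()
  for (i in ids) {
    a <- sum(lab == i)
    d <- 2 * sqrt(a / pi)
    if (d >= 5 && d <= 60) { kept_oracle <- kept_oracle + a; areas <- c(areas, a) }
  }
  expect_equal(res$occupied_area_fraction, 100 * kept_oracle / (300 * 300))
  expect_setequal(res$object_areas_px, areas)
  expect_identical(res$n_objects, length(areas))
})

test_that("diameter and eccentricity recover generator truth across seeds", {
  errs_d <- errs_e <- numeric(50)
  for (i in 1:50) {
    ax_major <- stats::runif(1, 100, 180)
    ax_minor <- stats::runif(1, 0.55, 1) * ax_major
    bf <- generate_brightfield(synthetic_spec_2d(seed = 1000 + i,
      main_axes_px = c(ax_major, ax_minor),
      angle_deg = stats::runif(1, 0, 180),
      n_satellites = 0, noise_sd = 0.02))
    m <- measure_diameter_eccentricity(segment_main_spheroid(bf$image),
                                       bf$pixel_size_um)
    errs_d[i] <- abs(m$diameter_um - bf$truth$diameter_um) / bf$truth$diameter_um
    errs_e[i] <- abs(m$eccentricity - bf$truth$eccentricity)
  }
  expect_lt(stats::median(errs_d), 0.02)
  expect_lt(stats::median(errs_e), 0.05)
})
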