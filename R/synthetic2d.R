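#' Specification for a synthetic brightfield spheroid image
#'
#' Describes a dark elliptical spheroid on a bright background surrounded by
#' small dark satellite aggregates (dissociated cells), as seen in multiwell
#' plate scans.
#'
#' @param seed integer seed.
#' @param pixel_size_um physical pixel size (micrometres).
#' @param image_size_px image side lengths (rows, cols).
#' @param main_axes_px full major and minor axis lengths of the main ellipse
#'   in pixels, `c(major, minor)`.
#' @param angle_deg rotation of the major axis, degrees counter-clockwise.
#' @param n_satellites number of satellite aggregates.
#' @param satellite_diameter_px_range allowed satellite diameters (pixels).
#' @param noise_sd additive Gaussian noise on the [0, 1] intensity scale.
#' @return a validated list of class `synthetic_spec_2d`.
#' @export
synthetic_spec_2d <- function(seed = 1L,
                              pixel_size_um = 0.65,
                              image_size_px = c(400L, 400L),
                              main_axes_px = c(160, 120),
                              angle_deg = 0,
                              n_satellites = 8L,
                              satellite_diameter_px_range = c(12, 30),
                              noise_sd = 0.01) {
  stopifnot(
    pixel_size_um > 0, length(image_size_px) == 2L, all(image_size_px >= 32L),
    length(main_axes_px) == 2L, all(main_axes_px >= 4),
    main_axes_px[1] >= main_axes_px[2],
    n_satellites >= 0L,
    length(satellite_diameter_px_range) == 2L,
    satellite_diameter_px_range[1] >= 2,
    diff(satellite_diameter_px_range) >= 0,
    noise_sd >= 0
  )
  structure(list(seed = as.integer(seed), pixel_size_um = pixel_size_um,
                 image_size_px = as.integer(image_size_px),
                 main_axes_px = main_axes_px, angle_deg = angle_deg,
                 n_satellites = as.integer(n_satellites),
                 satellite_diameter_px_range = satellite_diameter_px_range,
                 noise_sd = noise_sd),
            class = "synthetic_spec_2d")
}

#' Generate a synthetic brightfield plate image with ground truth
#'
#' Renders the main spheroid ellipse (dark, intensity ~0.2) on a bright
#' background (~0.85), adds disjoint dark satellites (~0.25), then Gaussian pixel
#' noise. Ground truth carries the analytic eccentricity of the generating
#' ellipse, the equivalent-circle diameter of its pixelized area, and the
#' satellite (loose-cell) area as a percentage of the image.
#'
#' @param spec a [synthetic_spec_2d()] object.
#' @return list with `image` (numeric matrix in [0, 1]), `truth` (list:
#'   `diameter_um`, `eccentricity`, `loose_area_pct`, `main_area_px`,
#'   `satellite_centers`, `satellite_radii_px`), and `pixel_size_um`.
#' @export
generate_brightfield <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec_2d"))
  set.seed(spec$seed)
  nr <- spec$image_size_px[1]; nc <- spec$image_size_px[2]
  a <- spec$main_axes_px[1] / 2; b <- spec$main_axes_px[2] / 2
  cy <- nr / 2; cx <- nc / 2
  th <- spec$angle_deg * pi / 180

  yy <- matrix(seq_len(nr) - 0.5, nr, nc) - cy
  xx <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc) - cx
  u <- cos(th) * xx + sin(th) * yy
  v <- -sin(th) * xx + cos(th) * yy
  main <- (u / a)^2 + (v / b)^2 <= 1

  img <- matrix(0.85, nr, nc)
  img[main] <- 0.2

  sat_mask <- matrix(FALSE, nr, nc)
  sat_centers <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("y", "x")))
  sat_radii <- numeric(0)
  if (spec$n_satellites > 0L) {
    rng <- spec$satellite_diameter_px_range
    # keep satellites clear of the main ellipse and of each other
    for (i in seq_len(spec$n_satellites)) {
      placed <- FALSE
      for (att in 1:500) {
        r <- stats::runif(1, rng[1], rng[2]) / 2
        py <- stats::runif(1, r + 2, nr - r - 2)
        px <- stats::runif(1, r + 2, nc - r - 2)
        uu <- cos(th) * (px - cx) + sin(th) * (py - cy)
        vv <- -sin(th) * (px - cx) + cos(th) * (py - cy)
        # conservatively inflate the ellipse by the satellite radius + 3 px
        if ((uu / (a + r + 3))^2 + (vv / (b + r + 3))^2 <= 1) next
        if (length(sat_radii) > 0) {
          dd <- sqrt((sat_centers[, 1] - py)^2 + (sat_centers[, 2] - px)^2)
          if (any(dd < sat_radii + r + 2)) next
        }
        disk <- (yy + cy - py)^2 + (xx + cx - px)^2 <= r^2
        sat_mask <- sat_mask | disk
        sat_centers <- rbind(sat_centers, c(py, px))
        sat_radii <- c(sat_radii, r)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place satellites disjointly; reduce n_satellites or their size",
             call. = FALSE)
    }
    img[sat_mask] <- 0.25
  }

  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
  img <- pmin(pmax(img, 0), 1)

  main_area <- sum(main)
  truth <- list(
    diameter_um = 2 * sqrt(main_area / pi) * spec$pixel_size_um,
    eccentricity = sqrt(1 - (b / a)^2),
    loose_area_pct = 100 * sum(sat_mask) / (nr * nc),
    main_area_px = main_area,
    satellite_centers = sat_centers,
    satellite_radii_px = sat_radii
  )
  list(image = img, truth = truth, pixel_size_um = spec$pixel_size_um)
}

#' Generate a synthetic two-channel cryosection z-stack with ground truth
#'
#' Builds a spheroid cross-section with an outer ring expressing an
#' Involucrin-like marker (channel A) and an inner disk expressing a
#' CK14-like marker (channel B). Channel A's amplitude is scaled so that the
#' ratio of integrated densities A/B equals `programmed_ratio` by
#' construction. Exactly three z-planes carry the sharp image; all other
#' planes are strongly blurred copies, emulating out-of-focus sections.
#'
#' @param seed integer seed.
#' @param n_z number of z-planes (>= 3).
#' @param programmed_ratio target integrated-density ratio channel A / B.
#' @param spheroid_radius_px radius of the section disk in pixels.
#' @param image_size_px image side length (square).
#' @param focused_planes indices of the three sharp planes; default is three
#'   around the middle of the stack.
#' @param noise_sd additive Gaussian noise (a.u., signal amplitude is ~100).
#' @return list with `channel_a`, `channel_b` (3D arrays, dim = (y, x, z)),
#'   and `truth` (list: `programmed_ratio`, `focused_plane_indices`,
#'   `ring_area_px`, `core_area_px`, `spheroid_area_px`).
#' @export
generate_cryosection <- function(seed = 1L, n_z = 9L, programmed_ratio = 2.0,
                                 spheroid_radius_px = 120,
                                 image_size_px = 320L,
                                 focused_planes = NULL,
                                 noise_sd = 0) {
  stopifnot(n_z >= 3L, programmed_ratio > 0, spheroid_radius_px >= 10,
            image_size_px > 2 * spheroid_radius_px + 10, noise_sd >= 0)
  if (is.null(focused_planes)) {
    mid <- ceiling(n_z / 2)
    focused_planes <- sort(unique(pmin(pmax(mid + c(-1L, 0L, 1L), 1L), n_z)))
    if (length(focused_planes) < 3L) focused_planes <- seq_len(3L)
  }
  focused_planes <- sort(as.integer(focused_planes))
  stopifnot(length(focused_planes) == 3L, all(focused_planes >= 1L),
            all(focused_planes <= n_z))
  set.seed(as.integer(seed))

  ns <- as.integer(image_size_px)
  cy <- ns / 2; cx <- ns / 2
  yy <- matrix(seq_len(ns) - 0.5, ns, ns) - cy
  xx <- matrix(rep(seq_len(ns) - 0.5, each = ns), ns, ns) - cx
  rr <- sqrt(yy^2 + xx^2)
  disk <- rr <= spheroid_radius_px
  core <- rr <= 0.6 * spheroid_radius_px              # CK14-like basal core
  ring <- disk & rr >= 0.75 * spheroid_radius_px      # Involucrin-like rim

  amp_b <- 100
  sum_b <- amp_b * sum(core)
  amp_a <- programmed_ratio * sum_b / sum(ring)       # forces ID_A/ID_B
  plane_a <- matrix(0, ns, ns); plane_a[ring] <- amp_a
  plane_a[disk & !ring] <- 6                          # faint tissue signal
  plane_b <- matrix(0, ns, ns); plane_b[core] <- amp_b
  plane_b[disk & !core] <- 6

  blur2d <- function(m, s) {
    a <- array(m, c(dim(m), 1L))
    gaussian_blur_3d(a, s)[, , 1]
  }
  mk_stack <- function(sharp) {
    st <- array(0, c(ns, ns, n_z))
    blurred <- blur2d(sharp, 8)
    for (k in seq_len(n_z))
      st[, , k] <- if (k %in% focused_planes) sharp else blurred
    if (noise_sd > 0)
      st <- st + array(stats::rnorm(length(st), 0, noise_sd), dim(st))
    st
  }

  list(channel_a = mk_stack(plane_a), channel_b = mk_stack(plane_b),
       truth = list(programmed_ratio = programmed_ratio,
                    focused_plane_indices = focused_planes,
                    ring_area_px = sum(ring), core_area_px = sum(core),
                    spheroid_area_px = sum(disk)))
}
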