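paraboloid_map <- function(cx = 500, cy = 600) {
  g <- expand.grid(x_um = seq(0, 1000, by = 50), y_um = seq(0, 1200, by = 50))
  pts <- tibble::tibble(
    x_um = g$x_um, y_um = g$y_um,
    thickness_um = 100 + ((g$x_um - cx)^2 + (g$y_um - cy)^2) / 1e4, w = 1)
  interpolate_map(pts, grid_um = 50)
}

test_that("the macula is the smoothed interior minimum with center tie-break", {
  map <- paraboloid_map()
  mac <- locate_macula(map)
  expect_lt(abs(mac[["x_um"]] - 500), 60)
  expect_lt(abs(mac[["y_um"]] - 600), 60)

  # constant map: tie broken toward the scan center
  g <- expand.grid(x_um = seq(0, 1000, by = 100), y_um = seq(0, 1000, by = 100))
  cmap <- interpolate_map(tibble::tibble(x_um = g$x_um, y_um = g$y_um,
                                         thickness_um = 5, w = 1), grid_um = 100)
  macc <- locate_macula(cmap)
  expect_equal(macc[["x_um"]], 500)
  expect_equal(macc[["y_um"]], 500)
})

test_that("ROI radius is the distance to the nearest scan edge", {
  b <- c(0, 7500, 0, 7500)
  roi <- roi_from_center(c(x_um = 3750, y_um = 3750), b)
  expect_equal(roi$radius_um, 3750)
  roi2 <- roi_from_center(c(x_um = 1000, y_um = 3750), b)
  expect_equal(roi2$radius_um, 1000)
  expect_warning(roi0 <- roi_from_center(c(x_um = 0, y_um = 3750), b), "radius is 0")
  expect_equal(roi0$radius_um, 0)
})

test_that("weighted mean thickness matches hand arithmetic", {
  pts <- tibble::tibble(x_um = c(0, 1), y_um = 0,
                        thickness_um = c(100, 300), w = c(1, 3))
  expect_equal(weighted_mean_thickness(pts), 250)
  pts$w <- c(2, 2)
  expect_equal(weighted_mean_thickness(pts), 200)
  expect_equal(weighted_mean_thickness(pts[2, ]), 300)
  # invariant under uniform weight rescaling
  pts$w <- c(1, 3) * 17.3
  expect_equal(weighted_mean_thickness(pts), 250)

  roi <- roi_from_center(c(x_um = 100, y_um = 100), c(0, 200, 0, 200))
  far <- tibble::tibble(x_um = 1e5, y_um = 1e5, thickness_um = 1, w = 1)
  expect_error(weighted_mean_thickness(far, roi), "no thickness points")
  zero_w <- tibble::tibble(x_um = 100, y_um = 100, thickness_um = 1, w = 0)
  expect_error(weighted_mean_thickness(zero_w, roi), "zero")
})

test_that("plane fits recover slopes, tilt and azimuth", {
  set.seed(55)
  n <- 300
  x <- runif(n, -3000, 3000); y <- runif(n, -3000, 3000)
  pts <- tibble::tibble(x_um = x + 3750, y_um = y + 3750,
                        thickness_um = 250 + 10 * (x / 1000), w = 1)
  roi <- roi_from_center(c(x_um = 3750, y_um = 3750), c(0, 7500, 0, 7500))
  pf <- fit_plane(pts, roi, "OD")
  expect_equal(pf$a, 10, tolerance = 1e-6)
  expect_equal(pf$b, 0, tolerance = 1e-6)
  expect_equal(pf$theta_deg, atan(0.01) * 180 / pi, tolerance = 1e-4)
  expect_equal(pf$phi_deg, 180, tolerance = 1e-4)   # normal points to the thin side

  # direct normal-equation oracle
  X <- cbind(1, (pts$x_um - 3750) / 1000, (pts$y_um - 3750) / 1000)
  beta <- solve(t(X) %*% X, t(X) %*% pts$thickness_um)
  expect_equal(pf$c, beta[1], tolerance = 1e-8)
  expect_equal(pf$a, beta[2], tolerance = 1e-8)

  # constant map has no tilt
  pts0 <- pts; pts0$thickness_um <- 123
  expect_equal(fit_plane(pts0, roi, "OD")$theta_deg, 0, tolerance = 1e-9)

  # mirrored OS input of an OD map gives the identical azimuth
  pts_os <- pts
  pts_os$x_um <- 7500 - pts$x_um
  pf_os <- fit_plane(pts_os, roi, "OS")
  expect_equal(pf_os$phi_deg, pf$phi_deg, tolerance = 1e-6)
  expect_equal(pf_os$theta_deg, pf$theta_deg, tolerance = 1e-6)

  expect_error(fit_plane(pts[1:3, ] |>
                           dplyr::mutate(x_um = 0, thickness_um = 1:3), NULL),
               "collinear|degenerate")
})

test_that("tidy and glance expose the plane fit in broom style", {
  set.seed(56)
  pts <- tibble::tibble(x_um = runif(20, 0, 100), y_um = runif(20, 0, 100),
                        thickness_um = runif(20, 200, 220), w = 1)
  pf <- fit_plane(pts, NULL, "OD")
  td <- tidy(pf)
  expect_named(td, c("term", "estimate"))
  expect_equal(nrow(td), 3)
  gl <- glance(pf)
  expect_true(all(c("theta_deg", "phi_deg", "n") %in% names(gl)))
})

test_that("quadrant contrasts are signed normalized differences", {
  roi <- roi_from_center(c(x_um = 0, y_um = 0), c(-1000, 1000, -1000, 1000))
  quad_pts <- function(sx, sy, v) {
    tibble::tibble(x_um = sx * runif(30, 100, 800),
                   y_um = sy * runif(30, 100, 800),
                   thickness_um = v, w = 1)
  }
  set.seed(57)
  # thickness 300 on the nasal half (x > 0), 200 on the temporal half (OD)
  pts <- dplyr::bind_rows(quad_pts(+1, -1, 300), quad_pts(-1, +1, 200),
                          quad_pts(+1, +1, 300), quad_pts(-1, -1, 200))
  expect_equal(quadrant_contrast(pts, "IN-ST", roi, "OD"), 0.2, tolerance = 1e-12)
  expect_equal(quadrant_contrast(pts, "SN-IT", roi, "OD"), 0.2, tolerance = 1e-12)

  # symmetric map: zero contrast
  sym <- dplyr::bind_rows(quad_pts(+1, -1, 250), quad_pts(-1, +1, 250))
  expect_equal(quadrant_contrast(sym, "IN-ST", roi, "OD"), 0)

  # mirroring the eye swaps nasal and temporal: the contrast flips sign
  pts_os <- pts
  pts_os$x_um <- -pts$x_um
  expect_equal(quadrant_contrast(pts_os, "IN-ST", roi, "OS"), 0.2,
               tolerance = 1e-12)
  expect_equal(quadrant_contrast(pts, "IN-ST", roi, "OS"), -0.2,
               tolerance = 1e-12)

  empty_q <- quad_pts(+1, -1, 100)
  expect_error(quadrant_contrast(empty_q, "IN-ST", roi, "OD"), "empty")
})

test_that("noisy planar point clouds recover tilt within tight bounds", {
  set.seed(58)
  n <- 2000
  theta0 <- 2.0 * pi / 180          # polar tilt of the plane normal
  phi0 <- 35 * pi / 180             # azimuth toward the thin side
  slope <- tan(theta0) * 1000       # um per mm
  a0 <- -slope * cos(phi0); b0 <- -slope * sin(phi0)
  x <- runif(n, -3000, 3000); y <- runif(n, -3000, 3000)
  t_um <- 260 + a0 * x / 1000 + b0 * y / 1000 + rnorm(n, 0, 10)
  pts <- tibble::tibble(x_um = x, y_um = y, thickness_um = t_um, w = 1)
  pf <- fit_plane(pts, NULL, "OD")
  expect_lt(abs(pf$theta_deg - 2.0), 0.5)
  dphi <- ((pf$phi_deg - 35 + 180) %% 360) - 180
  expect_lt(abs(dphi), 2)
})

test_that("descriptors are invariant under fundus translation", {
  set.seed(59)
  pts <- tibble::tibble(x_um = runif(200, 0, 2000), y_um = runif(200, 0, 2000),
                        thickness_um = runif(200, 150, 350), w = runif(200))
  roi <- roi_from_center(c(x_um = 1000, y_um = 1000), c(0, 2000, 0, 2000))
  m1 <- weighted_mean_thickness(pts, roi)
  c1 <- quadrant_contrast(pts, "IN-ST", roi, "OD")
  t1 <- fit_plane(pts, roi, "OD")$theta_deg
  sh <- pts
  sh$x_um <- sh$x_um + 5000; sh$y_um <- sh$y_um - 1200
  roi2 <- roi_from_center(c(x_um = 6000, y_um = -200), c(5000, 7000, -1200, 800))
  expect_equal(weighted_mean_thickness(sh, roi2), m1, tolerance = 1e-9)
  expect_equal(quadrant_contrast(sh, "IN-ST", roi2, "OD"), c1, tolerance = 1e-9)
  expect_equal(fit_plane(sh, roi2, "OD")$theta_deg, t1, tolerance = 1e-9)
})
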