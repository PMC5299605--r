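#' Locate the macula on a retinal thickness map
#'
#' The macular center is the global minimum of the retinal-thickness
#' lattice after a light Gaussian smoothing (scale 2 cells, normalized
#' over available cells so NA borders do not bias it). Ties are broken
#' toward the scan center. A minimum on the boundary of the valid region
#' is returned with a warning.
#'
#' @param retina_map A `thickness_map` from [retinal_thickness_map()].
#' @return Named numeric `c(x_um, y_um)`.
#' @export
locate_macula <- function(retina_map) {
  g <- retina_map$grid
  ok <- is.finite(g)
  if (!any(ok)) abort("retinal thickness map has no interior cells")
  g0 <- g
  g0[!ok] <- 0
  sm <- gaussian_blur(g0, 2, 2)
  wt <- gaussian_blur(ok * 1, 2, 2)
  sm <- sm / pmax(wt, 1e-12)
  sm[!ok] <- Inf
  mn <- min(sm)
  cand <- which(sm - mn <= 1e-9, arr.ind = TRUE)
  cx <- mean(range(retina_map$x_um)); cy <- mean(range(retina_map$y_um))
  d2 <- (retina_map$x_um[cand[, 2]] - cx)^2 + (retina_map$y_um[cand[, 1]] - cy)^2
  pick <- cand[order(d2, cand[, 2], cand[, 1])[1], , drop = FALSE]
  on_edge <- pick[1] %in% c(1, nrow(g)) || pick[2] %in% c(1, ncol(g)) ||
    !all(ok[pmax(pick[1] - 1, 1):pmin(pick[1] + 1, nrow(g)),
            pmax(pick[2] - 1, 1):pmin(pick[2] + 1, ncol(g))])
  if (on_edge) warn("macular minimum lies on the boundary of the mapped region")
  c(x_um = retina_map$x_um[pick[2]], y_um = retina_map$y_um[pick[1]])
}

#' Largest circle around a center inscribed in the scan rectangle
#'
#' @param center Named numeric `c(x_um, y_um)`.
#' @param bounds `c(xmin, xmax, ymin, ymax)` of the scanned region (um).
#' @return List of class `circular_roi` with `center_um`, `radius_um`.
#' @export
roi_from_center <- function(center, bounds) {
  r <- min(center[["x_um"]] - bounds[1], bounds[2] - center[["x_um"]],
           center[["y_um"]] - bounds[3], bounds[4] - center[["y_um"]])
  if (r <= 0) {
    warn("ROI center lies on or outside the scan rectangle; radius is 0")
    r <- max(r, 0)
  }
  structure(list(center_um = c(x_um = center[["x_um"]], y_um = center[["y_um"]]),
                 radius_um = r),
            class = "circular_roi")
}

points_in_roi <- function(points, roi) {
  d2 <- (points$x_um - roi$center_um[["x_um"]])^2 +
        (points$y_um - roi$center_um[["y_um"]])^2
  points[d2 <= roi$radius_um^2, , drop = FALSE]
}

#' Probability-weighted mean choroidal thickness inside an ROI
#'
#' `sum(w * thickness) / sum(w)` over the points inside the circle;
#' invariant under uniform rescaling of the weights.
#'
#' @param points Tibble with `x_um`, `y_um`, `thickness_um`, `w`.
#' @param roi A [roi_from_center()] circle; `NULL` uses all points.
#' @return Mean thickness in micrometres.
#' @export
weighted_mean_thickness <- function(points, roi = NULL) {
  if (!is.null(roi)) points <- points_in_roi(points, roi)
  if (nrow(points) == 0) abort("no thickness points inside the ROI")
  if (!any(points$w > 0)) abort("all point weights are zero inside the ROI")
  sum(points$w * points$thickness_um) / sum(points$w)
}

# Anatomical fundus frame: +x temporal -> nasal, +y inferior -> superior.
# OD maps are used as-is; OS maps are mirrored in x about the ROI center.
anatomical_xy <- function(points, center, laterality) {
  sgn <- if (laterality == "OS") -1 else 1
  tibble(
    x_mm = sgn * (points$x_um - center[["x_um"]]) / 1000,
    y_mm = (points$y_um - center[["y_um"]]) / 1000
  )
}

#' Weighted plane fit to a choroidal thickness map
#'
#' Fits `thickness = a*x + b*y + c` (thickness in um, fundus coordinates in
#' mm, weighted least squares with the node weights) over the ROI points
#' expressed in the anatomical frame (OS maps mirrored in x so the
#' nasal/temporal axis is consistent across eyes). The tilt of the map is
#' summarized by the spherical angles of the upward plane normal
#' `(-a, -b, 1)` (slopes converted to um/um): `theta_deg` is the polar
#' angle off +z, `phi_deg` the azimuth in the anatomical frame, pointing
#' toward the thin side of the map.
#'
#' @param points Tibble with `x_um`, `y_um`, `thickness_um`, `w`.
#' @param roi Optional [roi_from_center()]; its center defines the frame
#'   origin. `NULL` uses all points about their centroid.
#' @param laterality `"OD"` or `"OS"`.
#' @return Object of class `choroid_plane_fit` with `a`, `b`, `c`
#'   (um/mm, um/mm, um), `theta_deg`, `phi_deg`, `n`, and the underlying
#'   `lm` fit.
#' @export
fit_plane <- function(points, roi = NULL, laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  if (!is.null(roi)) {
    points <- points_in_roi(points, roi)
    center <- roi$center_um
  } else {
    center <- c(x_um = mean(points$x_um), y_um = mean(points$y_um))
  }
  if (nrow(points) < 3) abort("plane fit needs at least 3 points")
  xy <- anatomical_xy(points, center, laterality)
  df <- data.frame(t = points$thickness_um, x = xy$x_mm, y = xy$y_mm,
                   w = points$w)
  if (qr(cbind(1, df$x, df$y))$rank < 3) {
    abort("plane fit is degenerate: points are collinear in the fundus plane")
  }
  fit <- lm(t ~ x + y, data = df, weights = w)
  cf <- coef(fit)
  a <- cf[["x"]]; b <- cf[["y"]]; cc <- cf[["(Intercept)"]]
  # slopes in um per mm -> dimensionless um per um
  ax <- a * 1e-3; by <- b * 1e-3
  theta <- atan(sqrt(ax^2 + by^2)) * 180 / pi
  phi <- atan2(-by, -ax) * 180 / pi
  if (phi <= -180) phi <- phi + 360
  structure(list(a = a, b = b, c = cc, theta_deg = theta, phi_deg = phi,
                 n = nrow(df), laterality = laterality, center_um = center,
                 fit = fit),
            class = "choroid_plane_fit")
}

#' @export
print.choroid_plane_fit <- function(x, ...) {
  cat(sprintf(
    "<choroid_plane_fit> t = %.2f%+.2f x%+.2f y (um, mm) | theta %.2f deg, phi %.1f deg (%s)\n",
    x$c, x$a, x$b, x$theta_deg, x$phi_deg, x$laterality))
  invisible(x)
}

#' @export
#' @importFrom generics glance
#' @method glance choroid_plane_fit
glance.choroid_plane_fit <- function(x, ...) {
  tibble(theta_deg = x$theta_deg, phi_deg = x$phi_deg,
         mean_thickness_um = x$c, n = x$n, laterality = x$laterality)
}

#' @export
#' @method tidy choroid_plane_fit
tidy.choroid_plane_fit <- function(x, ...) {
  tibble(term = c("intercept_um", "slope_x_um_per_mm", "slope_y_um_per_mm"),
         estimate = c(x$c, x$a, x$b))
}

#' Thickness contrast between diagonal quadrants
#'
#' Computes `(m1 - m2) / (m1 + m2)` where `m1`, `m2` are the weighted mean
#' thicknesses of two diagonally opposite quadrants around the ROI center
#' in the anatomical frame. `"IN-ST"` contrasts inferior-nasal against
#' superior-temporal; `"SN-IT"` superior-nasal against inferior-temporal.
#'
#' @param points Tibble with `x_um`, `y_um`, `thickness_um`, `w`.
#' @param pair `"IN-ST"` or `"SN-IT"`.
#' @param roi [roi_from_center()] circle.
#' @param laterality `"OD"` or `"OS"`.
#' @return The signed contrast.
#' @export
quadrant_contrast <- function(points, pair = c("IN-ST", "SN-IT"), roi,
                              laterality = c("OD", "OS")) {
  pair <- match.arg(pair)
  laterality <- match.arg(laterality)
  points <- points_in_roi(points, roi)
  xy <- anatomical_xy(points, roi$center_um, laterality)
  quad <- function(sx, sy) points[sx * xy$x_mm > 0 & sy * xy$y_mm > 0, , drop = FALSE]
  qs <- switch(pair,
    "IN-ST" = list(quad(+1, -1), quad(-1, +1)),   # inferior-nasal vs superior-temporal
    "SN-IT" = list(quad(+1, +1), quad(-1, -1)))   # superior-nasal vs inferior-temporal
  if (nrow(qs[[1]]) == 0 || nrow(qs[[2]]) == 0) {
    abort(sprintf("quadrant pair %s has an empty quadrant inside the ROI", pair))
  }
  m1 <- weighted_mean_thickness(qs[[1]])
  m2 <- weighted_mean_thickness(qs[[2]])
  (m1 - m2) / (m1 + m2)
}

#' All 3-D choroid descriptors for one volume
#'
#' Convenience wrapper: locates the macula on the retinal map, builds the
#' largest inscribed circular ROI, and computes the weighted mean
#' thickness, plane-fit tilt and both diagonal quadrant contrasts from the
#' scattered choroidal points (never from the interpolated lattice).
#'
#' @param points Choroidal thickness points (tibble).
#' @param retina_map `thickness_map` of the retina.
#' @param bounds Scan rectangle `c(xmin, xmax, ymin, ymax)` in um.
#' @param laterality `"OD"` or `"OS"`.
#' @return A one-row tibble of descriptors.
#' @export
describe_choroid <- function(points, retina_map, bounds,
                             laterality = c("OD", "OS")) {
  laterality <- match.arg(laterality)
  mac <- locate_macula(retina_map)
  roi <- roi_from_center(mac, bounds)
  pf <- fit_plane(points, roi, laterality)
  tibble(
    macula_x_um = mac[["x_um"]], macula_y_um = mac[["y_um"]],
    roi_radius_um = roi$radius_um,
    mean_thickness_um = weighted_mean_thickness(points, roi),
    theta_deg = pf$theta_deg, phi_deg = pf$phi_deg,
    contrast_in_st = quadrant_contrast(points, "IN-ST", roi, laterality),
    contrast_sn_it = quadrant_contrast(points, "SN-IT", roi, laterality),
    n_points = nrow(points_in_roi(points, roi))
  )
}
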