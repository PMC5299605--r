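#' Parameters for RVI/RPE/BM segmentation
#'
#' @param sigma_pre_px Isotropic Gaussian pre-smoothing width (px) applied
#'   before gradient-peak detection.
#' @param poly_degree Degree of the polynomial used for outlier rejection.
#' @param outlier_k Rejection multiple: points deviating from the fit by more
#'   than `outlier_k` times the median absolute residual are discarded.
#' @param step_cap_px Maximum per-column axial step of the RPE-center path.
#' @param post_band_px Depth (px) of the band searched behind the RPE center
#'   for the posterior interface.
#' @param default_shift_px Fallback posterior shift when the band carries no
#'   intensity slope.
#' @param eps Small positive guard for divisions.
#' @return A list of class `rpe_bm_params`.
#' @export
rpe_bm_params <- function(sigma_pre_px = 3, poly_degree = 5, outlier_k = 5,
                          step_cap_px = 2, post_band_px = 12,
                          default_shift_px = 6, eps = 1e-6) {
  if (poly_degree < 1) abort("poly_degree must be >= 1")
  if (outlier_k <= 0) abort("outlier_k must be > 0")
  structure(list(sigma_pre_px = sigma_pre_px, poly_degree = poly_degree,
                 outlier_k = outlier_k, step_cap_px = step_cap_px,
                 post_band_px = post_band_px,
                 default_shift_px = default_shift_px, eps = eps),
            class = "rpe_bm_params")
}

#' Detect the RVI and RPE interfaces from axial gradient peaks
#'
#' After Gaussian pre-smoothing, the retina-vitreous interface and the
#' anterior RPE interface are found per column as the two highest local
#' maxima of the axial intensity gradient (most anterior peak = RVI). A
#' first estimate of the posterior RPE interface is taken at the first
#' negative local minimum of the gradient below the anterior interface.
#' Columns with fewer than two positive gradient maxima, or no posterior
#' minimum, are marked invalid.
#'
#' @param bscan Numeric matrix (rows = z, cols = x), intensities in
#'   `[0, 255]`.
#' @param params [rpe_bm_params()].
#' @return List with `layer_trace` elements `rvi`, `rpe_ant`, `rpe_post_est`.
#' @export
detect_rvi_rpe <- function(bscan, params = rpe_bm_params()) {
  sm <- gaussian_blur(bscan, params$sigma_pre_px, params$sigma_pre_px)
  g <- axial_gradient(sm)
  n_z <- nrow(g); n_x <- ncol(g)
  up <- g[2:(n_z - 1), , drop = FALSE]
  is_max <- up > g[1:(n_z - 2), , drop = FALSE] &
            up >= g[3:n_z, , drop = FALSE] & up > 0
  is_min <- up < g[1:(n_z - 2), , drop = FALSE] &
            up <= g[3:n_z, , drop = FALSE] & up < 0
  rvi <- rpe_a <- rpe_p <- rep(NA_real_, n_x)
  for (x in seq_len(n_x)) {
    zz <- which(is_max[, x]) + 1L            # row index in g
    if (length(zz) < 2L) next
    top2 <- zz[order(g[zz, x], decreasing = TRUE)[1:2]]
    top2 <- sort(top2)
    zn <- which(is_min[, x]) + 1L
    zn <- zn[zn > top2[2]]
    if (length(zn) == 0L) next
    rvi[x] <- top2[1] - 1L                   # 0-based
    rpe_a[x] <- top2[2] - 1L
    rpe_p[x] <- zn[1] - 1L
  }
  ok <- is.finite(rvi)
  if (!any(ok)) abort("RVI/RPE segmentation failed: no column has two gradient maxima")
  list(
    rvi = layer_trace(rvi, ok, layer = "RVI", n_z = n_z),
    rpe_ant = layer_trace(rpe_a, ok, layer = "RPE_CENTER", n_z = n_z),
    rpe_post_est = layer_trace(rpe_p, ok, layer = "RPE_POST", n_z = n_z)
  )
}

#' Polynomial-fit outlier rejection for a layer trace
#'
#' Fits a single polynomial (degree `poly_degree`, default 5) through the
#' valid columns, discards points whose residual exceeds `outlier_k` times
#' the median absolute residual, and replaces discarded (and originally
#' invalid) columns by linear interpolation between surviving neighbors,
#' extending the nearest surviving value at the edges. The fit is computed
#' once; the procedure is not iterated.
#'
#' @param trace A [layer_trace()].
#' @param params [rpe_bm_params()].
#' @return A fully valid `layer_trace` of the same length.
#' @export
reject_outliers <- function(trace, params = rpe_bm_params()) {
  ok <- trace$valid
  deg <- params$poly_degree
  if (sum(ok) < deg + 1) {
    warn("too few valid columns for outlier rejection; trace passed through")
    return(trace)
  }
  x <- trace$x_px[ok]
  z <- trace$z_px[ok]
  fit <- lm(z ~ poly(x, degree = deg, raw = TRUE))
  res <- abs(z - fitted(fit))
  mad0 <- median(res)
  keep <- if (mad0 > 0) res <= params$outlier_k * mad0 else rep(TRUE, length(res))
  zfull <- rep(NA_real_, nrow(trace))
  zfull[trace$x_px[ok][keep] + 1L] <- z[keep]
  layer_trace(fill_linear(zfull), layer = trace_layer(trace))
}

# Minimum-cost left-to-right path through a per-column band of a cost matrix.
# cost: n_z x n_x matrix; lo, hi: 0-based inclusive band bounds per column.
# Steps are column-to-next-column with |dz| <= cap; ties prefer smaller |dz|.
# Returns the 0-based z positions of the path.
band_min_path <- function(cost, lo, hi, cap) {
  n_z <- nrow(cost); n_x <- ncol(cost)
  lo <- pmax(0L, pmin(as.integer(round(lo)), n_z - 1L))
  hi <- pmax(lo, pmin(as.integer(round(hi)), n_z - 1L))
  zmin <- min(lo); zmax <- max(hi)
  nz <- zmax - zmin + 1L
  big <- Inf
  D <- matrix(big, nz, n_x)
  P <- matrix(NA_integer_, nz, n_x)
  band1 <- (lo[1] - zmin + 1L):(hi[1] - zmin + 1L)
  D[band1, 1] <- cost[(lo[1]:hi[1]) + 1L, 1]
  steps <- order(abs(seq(-cap, cap)))        # 0 first, then +/-1, ...
  dzs <- seq(-cap, cap)[steps]
  for (x in 2:n_x) {
    prev <- D[, x - 1L]
    best <- rep(big, nz)
    from <- rep(NA_integer_, nz)
    for (dz in dzs) {
      # state z came from z - dz
      src <- seq_len(nz) - dz
      okz <- src >= 1L & src <= nz
      cand <- rep(big, nz)
      cand[okz] <- prev[src[okz]]
      better <- cand < best                  # strict: earlier (smaller |dz|) wins ties
      best[better] <- cand[better]
      from[better] <- src[better]
    }
    band <- (lo[x] - zmin + 1L):(hi[x] - zmin + 1L)
    if (!any(is.finite(best[band]))) {
      # band unreachable from the previous column: restart the path here
      D[band, x] <- cost[(lo[x]:hi[x]) + 1L, x]
      P[band, x] <- -1L
    } else {
      D[band, x] <- best[band] + cost[(lo[x]:hi[x]) + 1L, x]
      P[band, x] <- from[band]
    }
  }
  # terminal state: minimal cost; ties -> closest to the band midpoint, then
  # the more anterior row
  fin <- D[, n_x]
  cand <- which(fin == min(fin))
  mid <- (lo[n_x] + hi[n_x]) / 2 - zmin + 1L
  cand <- cand[order(abs(cand - mid), cand)]
  zi <- cand[1]
  path <- integer(n_x)
  path[n_x] <- zi
  for (x in n_x:2) {
    zi <- P[path[x], x]
    if (is.na(zi) || zi == -1L) {
      # path restart: pick the cheapest state of the previous column
      prev <- D[, x - 1L]
      zi <- which(prev == min(prev))[1]
    }
    path[x - 1L] <- zi
  }
  path + zmin - 1L
}

#' Refine the RPE center with a brightest-ridge graph search
#'
#' Uses every pixel between the anterior and posterior RPE interfaces as a
#' node with cost `255 - intensity` and finds the minimum-cost
#' left-to-right path (one node per column, axial step capped at
#' `step_cap_px`, ties broken toward the smaller step), i.e. the brightest
#' ridge of the RPE band. Columns with an empty band take the band
#' midpoint.
#'
#' @param bscan Numeric matrix in `[0, 255]`.
#' @param rpe_ant,rpe_post_est Anterior/posterior band bounds
#'   ([layer_trace()]s, fully valid, e.g. after [reject_outliers()]).
#' @param params [rpe_bm_params()].
#' @return A `layer_trace` (layer `"RPE_CENTER"`), valid on all columns.
#' @export
refine_rpe_center <- function(bscan, rpe_ant, rpe_post_est,
                              params = rpe_bm_params()) {
  lo <- round(rpe_ant$z_px)
  hi <- round(rpe_post_est$z_px)
  swap <- hi < lo
  if (any(swap)) {
    mid <- (lo[swap] + hi[swap]) / 2
    lo[swap] <- hi[swap] <- round(mid)
  }
  z <- band_min_path(255 - bscan, lo, hi, cap = params$step_cap_px)
  layer_trace(z, layer = "RPE_CENTER", n_z = nrow(bscan))
}

#' Locate the posterior RPE interface at a fixed shift behind the center
#'
#' Traces a minimum-cost path in a band posterior to the RPE center using
#' `1 / (|dI/dz| + eps)` as node cost, so the path follows the strongest
#' intensity slope (the posterior RPE drop). The per-B-scan shift is the
#' median offset of this path from the center; the posterior interface is
#' the center shifted by that constant. A flat band (no slope anywhere)
#' falls back to `default_shift_px` with a warning.
#'
#' @param bscan Numeric matrix in `[0, 255]`.
#' @param rpe_center `layer_trace` from [refine_rpe_center()].
#' @param params [rpe_bm_params()].
#' @return List with `shift_px` (scalar, >= 0) and `rpe_post`
#'   (`layer_trace`).
#' @export
locate_posterior_rpe <- function(bscan, rpe_center, params = rpe_bm_params()) {
  n_z <- nrow(bscan)
  g <- abs(axial_gradient(bscan))
  lo <- pmin(round(rpe_center$z_px) + 1, n_z - 1)
  hi <- pmin(lo + params$post_band_px - 1, n_z - 1)
  band_max <- 0
  for (x in seq_len(ncol(bscan))) {
    band_max <- max(band_max, max(g[(lo[x]:hi[x]) + 1L, x]))
  }
  if (band_max < 1e-3) {
    warn("posterior RPE band carries no intensity slope; using the default shift")
    shift <- params$default_shift_px
  } else {
    z <- band_min_path(1 / (g + params$eps), lo, hi, cap = params$step_cap_px)
    # sub-pixel slope peak by quadratic interpolation around the path row
    zi <- pmin(pmax(z, 1L), n_z - 2L) + 1L
    cols <- seq_len(ncol(bscan))
    gm <- g[cbind(zi - 1L, cols)]; g0 <- g[cbind(zi, cols)]; gp <- g[cbind(zi + 1L, cols)]
    den <- gm - 2 * g0 + gp
    frac <- ifelse(abs(den) > 1e-12, 0.5 * (gm - gp) / den, 0)
    frac[!is.finite(frac) | abs(frac) > 1] <- 0
    shift <- median(z + frac - rpe_center$z_px)
    shift <- max(shift, 0)
  }
  layer <- layer_trace(rpe_center$z_px + shift, layer = "RPE_POST", n_z = n_z)
  list(shift_px = shift, rpe_post = layer)
}

# Posterior (maximum-z) chain of the convex hull of (x, z) points, evaluated
# at integer x by linear interpolation along the hull edges.
posterior_hull_chain <- function(x, z) {
  ord <- order(x, z)
  x <- x[ord]; z <- z[ord]
  # Andrew monotone chain, keeping the max-z side: right turns only
  hx <- numeric(0); hz <- numeric(0)
  cross <- function(ox, oz, ax, az, bx, bz) (ax - ox) * (bz - oz) - (az - oz) * (bx - ox)
  for (i in seq_along(x)) {
    while (length(hx) >= 2) {
      n <- length(hx)
      if (cross(hx[n - 1], hz[n - 1], hx[n], hz[n], x[i], z[i]) >= 0) {
        hx <- hx[-n]; hz <- hz[-n]
      } else break
    }
    hx <- c(hx, x[i]); hz <- c(hz, z[i])
  }
  list(x = hx, z = hz)
}

#' Estimate Bruch's membrane as the posterior convex hull of the RPE
#'
#' The BM is taken as the posterior-side chain of the 2-D convex hull of
#' the valid (x, z) points of the posterior RPE trace, evaluated at every
#' column by linear interpolation along the hull edges, then shifted
#' posteriorly by `shift_px`. Drusen, which locally pull the RPE
#' anteriorly, are bridged by straight hull chords.
#'
#' @param rpe_post `layer_trace` of the posterior RPE interface.
#' @param shift_px Additional posterior shift in pixels (default 0; the
#'   pipeline applies the slope shift in [locate_posterior_rpe()]).
#' @return A `layer_trace` (layer `"BM"`), valid wherever within the valid
#'   x-extent of `rpe_post`.
#' @export
bm_from_convex_hull <- function(rpe_post, shift_px = 0) {
  ok <- rpe_post$valid
  if (sum(ok) < 3) abort("convex-hull BM needs at least 3 valid columns")
  ch <- posterior_hull_chain(rpe_post$x_px[ok], rpe_post$z_px[ok])
  z <- approx(ch$x, ch$z, xout = rpe_post$x_px, rule = 1)$y + shift_px
  layer_trace(z, layer = "BM")
}

#' Segment RVI, RPE and BM on one B-scan
#'
#' Runs the full anterior pipeline: gradient-peak detection, polynomial
#' outlier rejection of each raw trace, RPE-center refinement, posterior
#' shift estimation, and convex-hull BM.
#'
#' @param bscan Numeric matrix in `[0, 255]`.
#' @param params [rpe_bm_params()].
#' @return List of `layer_trace`s: `rvi`, `rpe_center`, `rpe_post`, `bm`,
#'   plus `shift_px`.
#' @export
segment_rpe_bm <- function(bscan, params = rpe_bm_params()) {
  # isotropic low-pass for peak detection; for the ridge and slope searches
  # smoothing is concentrated along the boundary (x) so the axial position
  # of the posterior edge is not washed out
  det <- detect_rvi_rpe(bscan, params)
  sm_loc <- gaussian_blur(bscan, min(1, params$sigma_pre_px),
                          2 * params$sigma_pre_px)
  rvi <- reject_outliers(det$rvi, params)
  ant <- reject_outliers(det$rpe_ant, params)
  post0 <- reject_outliers(det$rpe_post_est, params)
  center <- refine_rpe_center(sm_loc, ant, post0, params)
  pp <- locate_posterior_rpe(sm_loc, center, params)
  # damp the +-1 px ridge wiggle before the hull: the posterior hull chain
  # would otherwise ride the local maxima of the noise
  post_s <- pp$rpe_post
  post_s$z_px <- smooth_vec(post_s$z_px, params$sigma_pre_px)
  bm <- bm_from_convex_hull(post_s, 0)
  list(rvi = rvi, rpe_center = center, rpe_post = pp$rpe_post, bm = bm,
       shift_px = pp$shift_px)
}
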