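#' Synthetic OCT phantom specification
#'
#' Builds a fully populated specification for [generate_phantom()]. The
#' phantom emulates the image features the segmentation relies on: a bright
#' retina-vitreous band, a bright RPE band whose posterior edge defines
#' Bruch's membrane, a darker choroidal stroma containing dark vessel
#' ellipses whose posterior rims abut a brighter sclera at the
#' choroid-sclera interface, optional drusen that raise the RPE band off
#' the BM, multiplicative speckle noise, and whole-pixel axial jitter
#' between B-scans (eye-motion surrogate).
#'
#' The default geometry is a 7.5 x 7.5 mm macular scan square covered by 50
#' B-scans of 512 (x) by 496 (z) pixels, with a 3.87 um axial pitch.
#'
#' Presets:
#' \describe{
#'   \item{clean}{no speckle, no jitter, no drusen}
#'   \item{noisy}{speckle coefficient of variation 0.30, jitter up to 8 px}
#'   \item{drusen}{four drusen, mild speckle (0.10) and jitter (2 px)}
#'   \item{low_contrast}{as noisy with the vessel intensity dip halved}
#' }
#'
#' @param preset One of `"clean"`, `"noisy"`, `"drusen"`, `"low_contrast"`.
#' @param ... Named overrides for any spec field (e.g. `n_bscans`, `seed`,
#'   `speckle_cv`, `vessels_per_bscan`).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(preset = c("clean", "noisy", "drusen", "low_contrast"), ...) {
  presets <- c("clean", "noisy", "drusen", "low_contrast")
  if (!is.character(preset) || !preset[1] %in% presets) {
    abort(sprintf("unknown preset '%s'; available presets: %s",
                  as.character(preset)[1], paste(presets, collapse = ", ")))
  }
  preset <- preset[1]
  span_um <- 7500
  spec <- list(
    preset = preset,
    n_x = 512L, n_z = 496L, n_bscans = 50L,
    dx_um = span_um / 512, dz_um = 3.87, dy_um = span_um / 49,
    span_um = span_um,
    # layer depths (um from the anterior image edge), smooth in (x, y)
    rvi_base_um = 220, rvi_pit_um = 150, rvi_pit_sigma_um = 900,
    rvi_band_um = 40,
    rpe_base_um = 560, rpe_sag_um = 60,      # posterior RPE edge = BM truth
    rpe_band_um = 26,
    choroid_base_um = 260, choroid_tilt_x = 0.012, choroid_tilt_y = -0.008,
    choroid_wave_um = 40, choroid_wave_period_um = 5200,
    drusen = data.frame(cx_um = numeric(0), cy_um = numeric(0),
                        r_um = numeric(0), h_um = numeric(0)),
    vessels_per_bscan = 12L, vessel_r_um = c(40, 90), vessel_dip = 70,
    # intensity levels in [0, 255]
    i_vitreous = 20, i_rvi_band = 230, i_retina = 90,
    i_rpe_band = 250, i_stroma = 110, i_sclera = 170,
    edge_w_um = 4, csi_w_um = 6,
    speckle_cv = 0, jitter_px = 0L, seed = 20170209L
  )
  spec <- switch(preset,
    clean = spec,
    noisy = modifyList(spec, list(speckle_cv = 0.30, jitter_px = 8L)),
    drusen = {
      spec$speckle_cv <- 0.10
      spec$jitter_px <- 2L
      spec$drusen <- data.frame(cx_um = c(2200, 3400, 4600, 5600),
                                cy_um = c(2600, 4400, 3000, 5200),
                                r_um = c(300, 240, 360, 260),
                                h_um = c(55, 40, 60, 45))
      spec
    },
    low_contrast = modifyList(spec, list(speckle_cv = 0.30, jitter_px = 8L,
                                         vessel_dip = 35))
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(spec))
    if (length(bad)) abort(sprintf("unknown phantom_spec field(s): %s",
                                   paste(bad, collapse = ", ")))
    for (nm in names(over)) spec[[nm]] <- over[[nm]]
  }
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

# Layer depth surfaces (um) at fundus coordinates; x, y in um.
phantom_layers <- function(spec, x_um, y_um) {
  cx <- spec$span_um / 2
  cy <- spec$span_um / 2
  r2 <- outer(rep(1, length(y_um)), (x_um - cx)^2) +
        outer((y_um - cy)^2, rep(1, length(x_um)))
  # RVI deepens toward the foveal pit so the retina thins centrally
  rvi <- spec$rvi_base_um + spec$rvi_pit_um * exp(-r2 / (2 * spec$rvi_pit_sigma_um^2))
  # posterior RPE edge: gentle posterior dome, concave in x per B-scan so the
  # posterior convex hull of the RPE reproduces it exactly
  sag <- spec$rpe_sag_um * (1 - ((outer(rep(1, length(y_um)), x_um) - cx) / cx)^2)
  rpe <- spec$rpe_base_um + sag
  thick <- spec$choroid_base_um +
    spec$choroid_tilt_x * (outer(rep(1, length(y_um)), x_um) - cx) +
    spec$choroid_tilt_y * (outer(y_um, rep(1, length(x_um))) - cy) +
    spec$choroid_wave_um *
      sin(2 * pi * outer(rep(1, length(y_um)), x_um) / spec$choroid_wave_period_um) *
      cos(2 * pi * outer(y_um, rep(1, length(x_um))) / spec$choroid_wave_period_um)
  csi <- rpe + thick
  list(rvi = rvi, rpe = rpe, csi = csi)
}

validate_phantom_spec <- function(spec) {
  x_um <- (seq_len(spec$n_x) - 0.5) * spec$dx_um
  y_um <- (seq_len(spec$n_bscans) - 0.5) * spec$dy_um
  ly <- phantom_layers(spec, x_um, y_um)
  if (!all(ly$rvi < ly$rpe) || !all(ly$rpe < ly$csi)) {
    abort("phantom layer ordering violated: need rvi_z < rpe_z < csi_z everywhere")
  }
  depth <- spec$n_z * spec$dz_um
  if (max(ly$csi) >= depth) abort("csi_z exceeds the image depth")
  invisible(spec)
}

#' Generate a synthetic OCT volume with exact ground truth
#'
#' Renders the phantom described by a [phantom_spec()] and returns both the
#' volume and the ground-truth layer traces (RVI, BM, CSI) at pixel centers,
#' including the axial jitter applied to each B-scan. With the speckle
#' strength at zero and no jitter the volume is a deterministic piecewise
#' smooth image; a fixed seed makes the noisy output reproducible.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` (an [oct_volume()]) and `truth`
#'   (list with `traces`, a per-B-scan list of `layer_trace` sets, `table`,
#'   the tidy trace table, and `jitter_px`, the applied per-B-scan offsets).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  set.seed(spec$seed)
  n_x <- spec$n_x; n_z <- spec$n_z; n_b <- spec$n_bscans
  x_um <- (seq_len(n_x) - 0.5) * spec$dx_um
  y_um <- (seq_len(n_b) - 0.5) * spec$dy_um
  z_um <- (seq_len(n_z) - 0.5) * spec$dz_um
  zmat <- matrix(z_um, n_z, n_x)

  jitter <- if (spec$jitter_px > 0) {
    sample.int(2L * spec$jitter_px + 1L, n_b, replace = TRUE) - spec$jitter_px - 1L
  } else rep(0L, n_b)

  logistic <- function(z0_row, w) {
    stats::plogis(sweep(zmat, 2, z0_row) / w)
  }

  bscans <- vector("list", n_b)
  truth <- vector("list", n_b)
  for (i in seq_len(n_b)) {
    ly <- phantom_layers(spec, x_um, y_um[i])
    rvi <- as.numeric(ly$rvi); rpe <- as.numeric(ly$rpe); csi <- as.numeric(ly$csi)
    # drusen raise the RPE band anteriorly but leave the BM (rpe) in place
    bump <- rep(0, n_x)
    if (nrow(spec$drusen) > 0) {
      for (k in seq_len(nrow(spec$drusen))) {
        d <- spec$drusen[k, ]
        rr2 <- (x_um - d$cx_um)^2 + (y_um[i] - d$cy_um)^2
        inside <- rr2 < d$r_um^2
        bump[inside] <- bump[inside] + d$h_um * cos(pi / 2 * sqrt(rr2[inside]) / d$r_um)^2
      }
    }
    w <- spec$edge_w_um
    img <- spec$i_vitreous +
      (spec$i_rvi_band - spec$i_vitreous) *
        (logistic(rvi, w) - logistic(rvi + spec$rvi_band_um, w)) +
      (spec$i_retina - spec$i_vitreous) * logistic(rvi + spec$rvi_band_um, w) +
      (spec$i_rpe_band - spec$i_retina) *
        (logistic(rpe - spec$rpe_band_um - bump, w) - logistic(rpe - bump, w)) +
      (spec$i_stroma - spec$i_retina) * logistic(rpe - bump, w) +
      (spec$i_sclera - spec$i_stroma) * logistic(csi, spec$csi_w_um)

    # dark vessels: filled ellipses with a smooth rim, posterior rim on the CSI
    if (spec$vessels_per_bscan > 0) {
      vx <- stats::runif(spec$vessels_per_bscan, 0, spec$span_um)
      vr <- stats::runif(spec$vessels_per_bscan, spec$vessel_r_um[1], spec$vessel_r_um[2])
      for (k in seq_len(spec$vessels_per_bscan)) {
        rx <- 2.2 * vr[k]              # vessels wider than tall in cross-section
        rz <- vr[k]
        cols <- which(abs(x_um - vx[k]) < 1.2 * rx)
        if (length(cols) == 0) next
        zc <- csi[cols] - rz           # posterior rim sits on the CSI
        ez <- (sweep(zmat[, cols, drop = FALSE], 2, zc))^2 / rz^2
        ex <- matrix((x_um[cols] - vx[k])^2 / rx^2, n_z, length(cols), byrow = TRUE)
        m <- stats::plogis((1 - (ex + ez)) / 0.08)
        img[, cols] <- img[, cols] - spec$vessel_dip * m
      }
    }

    # axial jitter: shift image content posteriorly by j pixels, edge replicate
    j <- jitter[i]
    if (j != 0) {
      src <- seq_len(n_z) - j
      src[src < 1L] <- 1L
      src[src > n_z] <- n_z
      img <- img[src, , drop = FALSE]
    }

    if (spec$speckle_cv > 0) {
      k_shape <- 1 / spec$speckle_cv^2
      noise <- matrix(stats::rgamma(n_z * n_x, shape = k_shape, rate = k_shape), n_z, n_x)
      img <- img * noise
    }
    img[img < 0] <- 0
    img[img > 255] <- 255
    bscans[[i]] <- img

    to_px <- function(um) um / spec$dz_um - 0.5 + j  # um depth -> 0-based px
    mk <- function(um, layer) {
      z <- to_px(um)
      layer_trace(z, valid = z >= 0 & z <= n_z - 1, layer = layer, n_z = n_z)
    }
    truth[[i]] <- list(RVI = mk(rvi, "RVI"), BM = mk(rpe, "BM"), CSI = mk(csi, "CSI"))
  }

  vol <- oct_volume(bscans, dx_um = spec$dx_um, dz_um = spec$dz_um,
                    positions = tibble(x0_um = rep(0.5 * spec$dx_um, n_b),
                                       y0_um = y_um),
                    laterality = "OD",
                    id = sprintf("phantom_%s_seed%d", spec$preset, spec$seed))
  list(volume = vol,
       truth = list(traces = truth, table = trace_table(truth), jitter_px = jitter))
}

#' Write a phantom volume and its ground truth to disk
#'
#' Writes a loadable volume directory (images + metadata, see
#' [write_oct_volume()]) and the ground-truth traces as TSV tables under
#' `file.path(out_dir, "truth")`.
#'
#' @param spec A [phantom_spec()].
#' @param out_dir Output directory.
#' @return Invisibly, `out_dir`.
#' @export
write_phantom <- function(spec, out_dir) {
  ph <- generate_phantom(spec)
  write_oct_volume(ph$volume, out_dir)
  export_traces(ph$truth$table, file.path(out_dir, "truth"))
  writeLines(yaml::as.yaml(list(preset = spec$preset, seed = spec$seed,
                                jitter_px = ph$truth$jitter_px)),
             file.path(out_dir, "truth", "phantom_info.yaml"))
  invisible(out_dir)
}
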