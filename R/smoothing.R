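#' Parameters for transverse (inter-B-scan) smoothing
#'
#' @param sigma_y_um Gaussian averaging scale across B-scans, in
#'   micrometres along the fundus y axis. `0` disables averaging (the
#'   volume is only flattened).
#' @param d_px Common flattening depth: the image row every Bruch's
#'   membrane is shifted to. `NULL` (default) uses half the image height.
#' @return A list of class `smoothing_params`.
#' @export
smoothing_params <- function(sigma_y_um = 200, d_px = NULL) {
  if (sigma_y_um < 0) abort("sigma_y_um must be >= 0")
  structure(list(sigma_y_um = sigma_y_um, d_px = d_px),
            class = "smoothing_params")
}

#' Flatten a B-scan to its Bruch's membrane
#'
#' Shifts each A-scan (column) by the integer `round(d_px - bm)` so the BM
#' lands on the common depth `d_px` (within half a pixel). Rows shifted in
#' from outside the image take the column's edge value.
#'
#' @param bscan Numeric matrix (rows = z).
#' @param bm Fully valid BM [layer_trace()].
#' @param d_px Target depth (0-based row), inside `[0, n_z)`.
#' @return List with `bscan` (flattened matrix) and `shifts` (per-column
#'   integer shift, positive = moved posteriorly).
#' @export
flatten_bscan <- function(bscan, bm, d_px) {
  n_z <- nrow(bscan)
  if (d_px < 0 || d_px >= n_z) abort("d_px must lie inside [0, n_z)")
  shifts <- as.integer(round(d_px - bm$z_px))
  if (any(!is.finite(shifts))) abort("flattening needs a BM value at every column")
  out <- bscan
  for (s in unique(shifts)) {
    cols <- which(shifts == s)
    if (s == 0L) next
    src <- seq_len(n_z) - s
    src[src < 1L] <- 1L
    src[src > n_z] <- n_z
    out[, cols] <- bscan[src, cols, drop = FALSE]
  }
  list(bscan = out, shifts = shifts)
}

#' Undo [flatten_bscan()]
#'
#' Exact inverse on rows whose source stayed inside the image.
#'
#' @param flat Flattened matrix.
#' @param shifts Per-column shifts returned by [flatten_bscan()].
#' @return The unflattened matrix.
#' @export
unflatten_bscan <- function(flat, shifts) {
  n_z <- nrow(flat)
  out <- flat
  for (s in unique(shifts)) {
    cols <- which(shifts == s)
    if (s == 0L) next
    src <- seq_len(n_z) + s
    src[src < 1L] <- 1L
    src[src > n_z] <- n_z
    out[, cols] <- flat[src, cols, drop = FALSE]
  }
  out
}

#' Gaussian averaging of flattened, registered neighboring B-scans
#'
#' Each B-scan is flattened to its BM (registration reference) and replaced
#' by the Gaussian-weighted average of its flattened neighbors within a
#' half-window `N = ceil(3 * sigma_y_um / dy_um)`; weights are renormalized
#' over the part of the window inside the stack, so they always sum to one.
#' B-scans whose BM is missing are excluded from their neighbors' averages.
#' The result is returned in the flattened frame (the CSI search consumes
#' flattened images); `shifts` allow mapping back via [unflatten_bscan()].
#'
#' @param vol An [oct_volume()].
#' @param bms Per-B-scan list of fully valid BM traces (or `NULL` entries
#'   for failed B-scans).
#' @param params [smoothing_params()].
#' @return List with `volume` (flattened, smoothed [oct_volume()]),
#'   `shifts` (per-B-scan integer vectors), and `d_px`.
#' @export
transverse_smooth <- function(vol, bms, params = smoothing_params()) {
  n <- n_bscans(vol)
  n_z <- nrow(vol$bscans[[1]])
  d_px <- params$d_px %||% floor(n_z / 2)
  have <- !vapply(bms, is.null, logical(1))
  flats <- vector("list", n)
  shifts <- vector("list", n)
  for (i in which(have)) {
    fl <- flatten_bscan(vol$bscans[[i]], bms[[i]], d_px)
    flats[[i]] <- fl$bscan
    shifts[[i]] <- fl$shifts
  }
  sigma_idx <- if (vol$dy_um > 0) params$sigma_y_um / vol$dy_um else 0
  N <- if (sigma_idx > 0) ceiling(3 * sigma_idx) else 0L
  out <- vector("list", n)
  for (i in which(have)) {
    js <- max(1L, i - N):min(n, i + N)
    js <- js[have[js]]
    w <- if (sigma_idx > 0) dnorm(js - i, sd = sigma_idx) else as.numeric(js == i)
    w <- w / sum(w)
    acc <- flats[[js[1]]] * w[1]
    if (length(js) > 1) {
      for (k in 2:length(js)) acc <- acc + flats[[js[k]]] * w[k]
    }
    out[[i]] <- acc
  }
  if (!all(have)) {
    # keep the stack aligned: unsmoothable B-scans stay raw and unshifted
    for (i in which(!have)) {
      out[[i]] <- vol$bscans[[i]]
      shifts[[i]] <- rep(0L, ncol(vol$bscans[[i]]))
    }
  }
  sm <- vol
  sm$bscans <- out
  list(volume = sm, shifts = shifts, d_px = d_px)
}
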