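#' Extract a manual annotation trace from a colored overlay image
#'
#' Manual segmentations drawn in a pure color on top of a B-scan are
#' recovered by locating the pixels within `tol` of the annotation color,
#' estimating per column the mean row position and its spread, discarding
#' columns whose spread exceeds three times the estimated line thickness
#' (median spread, floored at half a pixel), and interpolating the
#' survivors with a natural cubic spline across the surviving extent.
#'
#' @param image Either an `h x w x 3` RGB array in `[0, 1]` (e.g. from
#'   [png::readPNG()]) or a path to a PNG file.
#' @param color Length-3 RGB triple in `[0, 1]`.
#' @param tol Per-channel tolerance (default 0.1).
#' @param spread_mult Column-discard multiple of the line thickness
#'   (default 3).
#' @return An object of class `annotation_trace`: tibble with columns
#'   `x_px`, `z_px`, `valid`, plus attributes `line_thickness` and
#'   `columns` (per-column mean/spread table).
#' @export
extract_annotation <- function(image, color, tol = 0.1, spread_mult = 3) {
  if (is.character(image)) image <- png::readPNG(image)
  if (length(dim(image)) != 3 || dim(image)[3] < 3) {
    abort("annotation image must be an RGB array")
  }
  hit <- abs(image[, , 1] - color[1]) <= tol &
         abs(image[, , 2] - color[2]) <= tol &
         abs(image[, , 3] - color[3]) <= tol
  if (!any(hit)) abort("no pixels match the annotation color")
  n_x <- ncol(hit)
  zbar <- sig <- rep(NA_real_, n_x)
  for (x in seq_len(n_x)) {
    zz <- which(hit[, x]) - 1L
    if (length(zz) == 0) next
    zbar[x] <- mean(zz)
    sig[x] <- if (length(zz) > 1) sd(zz) else 0
  }
  cols <- which(is.finite(zbar))
  line_thickness <- max(median(sig[cols]), 0.5)
  keep <- cols[sig[cols] <= spread_mult * line_thickness]
  if (length(keep) < 2) abort("annotation too scattered: fewer than 2 usable columns")
  span <- keep[1]:keep[length(keep)]
  zs <- spline(keep, zbar[keep], xout = span, method = "natural")$y
  z <- rep(NA_real_, n_x)
  z[span] <- zs
  tr <- layer_trace(z, layer = "CSI")
  class(tr) <- c("annotation_trace", class(tr))
  attr(tr, "line_thickness") <- line_thickness
  attr(tr, "columns") <- tibble(x_px = cols - 1L, z_mean = zbar[cols],
                                z_sd = sig[cols])
  tr
}

#' Mean trace over several evaluators
#'
#' Per-column mean over the traces valid there; a column is invalid when
#' fewer than two traces cover it.
#'
#' @param traces List of at least two [layer_trace()]s of equal length.
#' @return A `layer_trace`.
#' @export
ground_truth_mean <- function(traces) {
  if (length(traces) < 2) abort("ground truth needs at least 2 traces")
  n <- nrow(traces[[1]])
  Z <- vapply(traces, function(t) {
    if (nrow(t) != n) abort("traces must have equal length")
    ifelse(t$valid, t$z_px, NA_real_)
  }, numeric(n))
  cnt <- rowSums(is.finite(Z))
  z <- rowMeans(Z, na.rm = TRUE)
  layer_trace(ifelse(cnt >= 2, z, NA_real_), layer = trace_layer(traces[[1]]))
}

#' Deviation of a trace from a ground-truth trace
#'
#' Absolute axial distance per shared valid column, scaled to micrometres,
#' with a median/IQR summary. Identically zero (and symmetric) when the
#' trace equals the truth.
#'
#' @param trace,truth [layer_trace()]s of equal length.
#' @param dz_um Axial pixel pitch (um/px); default 1 reports pixels.
#' @return List with `per_column` (tibble `x_px`, `dev_um`), `median_um`,
#'   `iqr_um`, `n`.
#' @export
deviation_stats <- function(trace, truth, dz_um = 1) {
  if (nrow(trace) != nrow(truth)) abort("trace and truth must have equal length")
  ok <- trace$valid & truth$valid
  if (!any(ok)) abort("trace and truth share no valid columns")
  dev <- abs(trace$z_px[ok] - truth$z_px[ok]) * dz_um
  list(per_column = tibble(x_px = trace$x_px[ok], dev_um = dev),
       median_um = median(dev), iqr_um = IQR(dev), n = sum(ok))
}
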