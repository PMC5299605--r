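#' Per-node choroidal thickness points
#'
#' Converts BM and CSI traces of one B-scan (in a common, typically
#' flattened, coordinate frame) into scattered fundus-space thickness
#' samples: one point per valid CSI column with
#' `thickness_um = (csi - bm) * dz_um`, weighted by the node's edge
#' probability. Columns where the CSI sits anterior to the BM are dropped
#' with a warning count attribute.
#'
#' @param csi_nodes Tibble with `x_px`, `z_px`, `p` (kept CSI nodes).
#' @param bm_flat BM [layer_trace()] in the same frame.
#' @param vol The source [oct_volume()].
#' @param bscan_idx 0-based B-scan index into `vol`.
#' @return Tibble with columns `x_um`, `y_um`, `thickness_um`, `w`; the
#'   number of dropped anterior points is in `attr(, "n_dropped")`.
#' @export
node_thickness <- function(csi_nodes, bm_flat, vol, bscan_idx) {
  pos <- vol$positions[bscan_idx + 1L, ]
  bmz <- bm_flat$z_px[match(csi_nodes$x_px, bm_flat$x_px)]
  dz <- csi_nodes$z_px - bmz
  bad <- !is.finite(dz) | dz < 0
  if (any(bad)) {
    warn(sprintf("%d CSI node(s) anterior to the BM dropped on B-scan %d",
                 sum(bad), bscan_idx))
  }
  out <- tibble(
    x_um = pos$x0_um + csi_nodes$x_px[!bad] * vol$dx_um,
    y_um = pos$y0_um + 0 * csi_nodes$x_px[!bad],
    thickness_um = dz[!bad] * vol$dz_um,
    w = csi_nodes$p[!bad]
  )
  attr(out, "n_dropped") <- sum(bad)
  out
}

#' Interpolate scattered thickness points onto a regular lattice
#'
#' Natural-neighbor ([nn_interpolate()]) interpolation of the points on a
#' square lattice of cell size `grid_um` covering `bounds` (by default the
#' bounding rectangle of the points). Cells outside the convex hull of the
#' points are `NA`.
#'
#' @param points Tibble with `x_um`, `y_um`, `thickness_um` and optionally
#'   `w`.
#' @param grid_um Lattice cell size (micrometres, default 50).
#' @param bounds Optional list/vector `c(xmin, xmax, ymin, ymax)` in um.
#' @return An object of class `thickness_map`: list with `points`, `grid`
#'   (matrix, rows = y), `x_um`, `y_um` (cell centers), `cell_um`,
#'   `bounds`.
#' @export
interpolate_map <- function(points, grid_um = 50, bounds = NULL) {
  if (nrow(points) < 3) abort("interpolation needs at least 3 points")
  if (is.null(bounds)) {
    bounds <- c(min(points$x_um), max(points$x_um),
                min(points$y_um), max(points$y_um))
  }
  xg <- seq(bounds[1], bounds[2], by = grid_um)
  yg <- seq(bounds[3], bounds[4], by = grid_um)
  qq <- expand.grid(x = xg, y = yg)
  vals <- nn_interpolate(points$x_um, points$y_um, points$thickness_um,
                         qq$x, qq$y)
  grid <- matrix(vals, nrow = length(yg), ncol = length(xg), byrow = TRUE)
  structure(list(points = as_tibble(points), grid = grid, x_um = xg, y_um = yg,
                 cell_um = grid_um, bounds = bounds),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf(
    "<thickness_map> %d points, %d x %d cells of %.0f um, thickness %.0f-%.0f um\n",
    nrow(x$points), ncol(x$grid), nrow(x$grid), x$cell_um,
    min(x$grid, na.rm = TRUE), max(x$grid, na.rm = TRUE)))
  invisible(x)
}

#' Tidy lattice of a thickness map
#'
#' @param x A `thickness_map`.
#' @param ... Unused.
#' @return Tibble with `x_um`, `y_um`, `thickness_um` (NA outside the
#'   interpolation hull).
#' @export
#' @importFrom generics tidy
#' @method tidy thickness_map
tidy.thickness_map <- function(x, ...) {
  tibble(
    x_um = rep(x$x_um, times = length(x$y_um)),
    y_um = rep(x$y_um, each = length(x$x_um)),
    thickness_um = as.numeric(t(x$grid))
  )
}

#' Retinal thickness map from RVI and BM traces
#'
#' Subtracts the RVI from the BM in every B-scan (both in the raw frame),
#' collects the per-column thicknesses as unit-weight points, and
#' interpolates them like [interpolate_map()].
#'
#' @param rvis,bms Per-B-scan lists of RVI and BM traces (raw frame).
#' @param vol The [oct_volume()].
#' @param grid_um Lattice cell size.
#' @param stride Column subsampling step for the scattered points
#'   (default 4; the retina is smooth at this scale).
#' @return A `thickness_map`.
#' @export
retinal_thickness_map <- function(rvis, bms, vol, grid_um = 50, stride = 4L) {
  pts <- purrr::map_dfr(seq_along(bms), function(i) {
    rv <- rvis[[i]]; bm <- bms[[i]]
    if (is.null(rv) || is.null(bm)) return(NULL)
    ok <- rv$valid & bm$valid & (rv$x_px %% stride == 0L)
    tibble(
      x_um = vol$positions$x0_um[i] + rv$x_px[ok] * vol$dx_um,
      y_um = vol$positions$y0_um[i],
      thickness_um = pmax(bm$z_px[ok] - rv$z_px[ok], 0) * vol$dz_um,
      w = 1
    )
  })
  interpolate_map(pts, grid_um = grid_um)
}

#' Fraction of successfully segmented B-scans
#'
#' @param segmented Logical vector: [bscan_segmented()] per B-scan.
#' @return A number in `[0, 1]`.
#' @export
success_fraction <- function(segmented) {
  if (length(segmented) == 0) abort("no B-scans")
  mean(segmented)
}

#' Export a thickness map as TSV tables and a PNG rendering
#'
#' Writes the scattered points (`<stem>_points.tsv`), the interpolated
#' lattice in long form (`<stem>_grid.tsv`), and a color-mapped PNG
#' (`<stem>.png`, viridis scale, NA transparent).
#'
#' @param map A `thickness_map`.
#' @param stem Output path stem (no extension).
#' @return Invisibly, the paths written.
#' @export
export_map <- function(map, stem) {
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  p1 <- paste0(stem, "_points.tsv")
  utils::write.table(format(as.data.frame(map$points), digits = 10, trim = TRUE),
                     p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- paste0(stem, "_grid.tsv")
  utils::write.table(format(as.data.frame(tidy.thickness_map(map)), digits = 10,
                            trim = TRUE),
                     p2, sep = "\t", quote = FALSE, row.names = FALSE)
  p3 <- paste0(stem, ".png")
  g <- map$grid
  rng <- range(g, na.rm = TRUE)
  gn <- if (diff(rng) > 0) (g - rng[1]) / diff(rng) else g * 0
  cols <- grDevices::hcl.colors(256, "viridis")
  idx <- pmin(pmax(round(gn * 255) + 1L, 1L), 256L)
  rgb <- grDevices::col2rgb(cols[idx]) / 255
  arr <- array(0, c(nrow(g), ncol(g), 4))
  arr[, , 1] <- matrix(rgb[1, ], nrow(g)); arr[, , 2] <- matrix(rgb[2, ], nrow(g))
  arr[, , 3] <- matrix(rgb[3, ], nrow(g)); arr[, , 4] <- !is.na(g)
  # image rows run top-down while y runs bottom-up
  png::writePNG(arr[rev(seq_len(nrow(g))), , , drop = FALSE], p3)
  invisible(c(p1, p2, p3))
}
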