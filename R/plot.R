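#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_point geom_line
#'   scale_fill_viridis_c coord_equal labs theme_minimal facet_wrap
NULL

#' Plot a thickness map
#'
#' Raster of the interpolated lattice (mm axes, viridis scale); the
#' anatomical frame note in the subtitle records the laterality handling
#' used by the descriptors.
#'
#' @param object A `thickness_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot thickness_map
autoplot.thickness_map <- function(object, ...) {
  df <- tidy.thickness_map(object)
  ggplot(df, aes(.data$x_um / 1000, .data$y_um / 1000,
                 fill = .data$thickness_um)) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "transparent", name = "thickness (µm)") +
    coord_equal() +
    labs(x = "x (mm)", y = "y (mm)",
         subtitle = "anatomical frame: +x temporal→nasal (OD; OS mirrored), +y inferior→superior") +
    theme_minimal()
}

#' Plot a B-scan with its segmented boundaries
#'
#' @param vol An [oct_volume()].
#' @param traces Tidy trace table (e.g. `result$traces`).
#' @param bscan_index 0-based B-scan index.
#' @return A ggplot (image in gray, one colored line per layer).
#' @export
plot_bscan_traces <- function(vol, traces, bscan_index = 0L) {
  b <- vol$bscans[[bscan_index + 1L]]
  img <- tibble(
    x = rep(seq_len(ncol(b)) - 1L, each = nrow(b)),
    z = rep(seq_len(nrow(b)) - 1L, times = ncol(b)),
    i = as.numeric(b)
  )
  tr <- traces[traces$bscan_index == bscan_index & traces$valid, , drop = FALSE]
  ggplot(img, aes(.data$x, .data$z)) +
    geom_raster(aes(fill = .data$i), show.legend = FALSE) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    geom_line(data = tr, aes(.data$x_px, .data$z_px, color = .data$layer),
              linewidth = 0.4, na.rm = TRUE) +
    ggplot2::scale_y_reverse() +
    coord_equal() +
    labs(x = "x (px)", y = "z (px)", color = NULL) +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
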