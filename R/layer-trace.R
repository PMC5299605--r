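#' Per-B-scan layer trace
#'
#' A layer trace records, for one B-scan, the axial (z) position of a retinal
#' or choroidal boundary at every image column (A-scan). Positions are real
#' valued (sub-pixel allowed) and 0-based: z = 0 is the anterior (top) image
#' row. Columns where the boundary could not be determined carry
#' `valid = FALSE` and `z_px = NA`.
#'
#' @param z_px Numeric vector of axial positions in pixels (0-based), `NA`
#'   where invalid.
#' @param valid Logical vector the same length as `z_px`; defaults to
#'   `is.finite(z_px)`.
#' @param layer Layer label, one of `"RVI"`, `"RPE_CENTER"`, `"RPE_POST"`,
#'   `"BM"`, `"CSI"`.
#' @param n_z Optional image height used to check `0 <= z_px <= n_z - 1`.
#'
#' @return A tibble of class `layer_trace` with columns `x_px` (0-based
#'   column index), `z_px` and `valid`, and a `layer` attribute.
#' @export
layer_trace <- function(z_px, valid = is.finite(z_px),
                        layer = c("RVI", "RPE_CENTER", "RPE_POST", "BM", "CSI"),
                        n_z = NULL) {
  layer <- match.arg(layer)
  z_px <- as.numeric(z_px)
  valid <- as.logical(valid)
  if (length(valid) != length(z_px)) abort("`valid` must match `z_px` in length")
  if (any(valid & !is.finite(z_px))) abort("valid columns must have finite z_px")
  if (!is.null(n_z) && any(valid & (z_px < 0 | z_px > n_z - 1))) {
    abort("z_px out of [0, n_z - 1] on a valid column")
  }
  z_px[!valid] <- NA_real_
  out <- tibble(x_px = seq_along(z_px) - 1L, z_px = z_px, valid = valid)
  class(out) <- c("layer_trace", class(out))
  attr(out, "layer") <- layer
  out
}

trace_layer <- function(trace) attr(trace, "layer") %||% "?"

#' @export
print.layer_trace <- function(x, ...) {
  cat(sprintf("<layer_trace> %s: %d columns, %d valid\n",
              trace_layer(x), nrow(x), sum(x$valid)))
  NextMethod()
}

# Shift a trace axially by a constant (used for flattening bookkeeping).
shift_trace <- function(trace, dz) {
  trace$z_px <- trace$z_px + dz
  trace
}

#' Combine per-B-scan traces into one tidy table
#'
#' @param traces A list (one element per B-scan) of named lists of
#'   [layer_trace()] objects, e.g. `traces[[i]]$BM`.
#' @return A tibble with columns `bscan_index` (0-based), `layer`, `x_px`,
#'   `z_px`, `valid`.
#' @export
trace_table <- function(traces) {
  purrr::imap_dfr(traces, function(set, i) {
    purrr::imap_dfr(set, function(tr, nm) {
      tibble(bscan_index = as.integer(i) - 1L, layer = trace_layer(tr),
             x_px = tr$x_px, z_px = tr$z_px, valid = tr$valid)
    })
  })
}

#' Export layer traces as tab-separated tables
#'
#' Writes one TSV per layer with columns `bscan_index`, `x_px`, `z_px`,
#' `valid`. Invalid columns are written with an empty `z_px` field and
#' `valid = 0`. Values round-trip through [read_traces()] to within 1e-6.
#'
#' @param traces Either a tidy trace table (see [trace_table()]) or a list of
#'   per-B-scan named lists of traces.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_traces <- function(traces, out_dir) {
  if (!is.data.frame(traces)) traces <- trace_table(traces)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) abort(sprintf("cannot create directory '%s'", out_dir))
  }
  paths <- character(0)
  for (ly in unique(traces$layer)) {
    sub <- traces[traces$layer == ly, , drop = FALSE]
    path <- file.path(out_dir, paste0("trace_", ly, ".tsv"))
    z_chr <- ifelse(sub$valid, sprintf("%.6f", sub$z_px), "")
    df <- data.frame(bscan_index = sub$bscan_index, x_px = sub$x_px,
                     z_px = z_chr, valid = as.integer(sub$valid))
    ok <- tryCatch({
      utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) abort(sprintf("cannot write trace table '%s'", path))
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read layer traces written by [export_traces()]
#'
#' @param dir Directory containing `trace_<LAYER>.tsv` files.
#' @param layers Optional subset of layer names to read.
#' @return A tidy trace table (tibble).
#' @export
read_traces <- function(dir, layers = NULL) {
  files <- list.files(dir, pattern = "^trace_.*\\.tsv$", full.names = TRUE)
  if (!is.null(layers)) {
    files <- files[sub("^trace_(.*)\\.tsv$", "\\1", basename(files)) %in% layers]
  }
  if (length(files) == 0) abort(sprintf("no trace tables found in '%s'", dir))
  purrr::map_dfr(files, function(f) {
    ly <- sub("^trace_(.*)\\.tsv$", "\\1", basename(f))
    df <- utils::read.table(f, sep = "\t", header = TRUE,
                            colClasses = c("integer", "integer", "numeric", "integer"),
                            na.strings = "")
    tibble(bscan_index = df$bscan_index, layer = ly, x_px = df$x_px,
           z_px = df$z_px, valid = df$valid == 1L)
  })
}

# Rebuild a per-B-scan list of layer_trace objects from a tidy trace table.
traces_from_table <- function(tbl) {
  idx <- sort(unique(tbl$bscan_index))
  lapply(idx, function(i) {
    sub <- tbl[tbl$bscan_index == i, , drop = FALSE]
    out <- list()
    for (ly in unique(sub$layer)) {
      s <- sub[sub$layer == ly, , drop = FALSE]
      s <- s[order(s$x_px), , drop = FALSE]
      out[[ly]] <- layer_trace(s$z_px, s$valid, layer = ly)
    }
    out
  })
}
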