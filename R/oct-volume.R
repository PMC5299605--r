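#' OCT volume container
#'
#' An `oct_volume` is an ordered stack of grayscale B-scans together with the
#' physical scales needed to interpret it: the in-plane pixel pitches
#' `dx_um` (transverse) and `dz_um` (axial), the inter-B-scan spacing
#' `dy_um`, the fundus position of every B-scan, and the eye laterality.
#' Intensities are stored as real numbers rescaled to `[0, 255]`.
#'
#' Coordinate convention: within a B-scan matrix, rows are the axial (z)
#' direction with z = 0 at the anterior (top) edge increasing posteriorly,
#' and columns are the transverse (x) direction. The y axis runs across
#' B-scans. All pixel indices exposed in traces are 0-based.
#'
#' @param bscans List of numeric matrices, all the same shape, ordered by
#'   ascending fundus y position.
#' @param dx_um,dz_um Pixel pitch in x and z, micrometres per pixel.
#' @param dy_um Spacing between consecutive B-scans (micrometres). If `NULL`,
#'   derived from `positions`.
#' @param positions Data frame with columns `x0_um`, `y0_um`: the fundus
#'   coordinate of the first A-scan of each B-scan.
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye).
#' @param id Free-text volume identifier.
#'
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(bscans, dx_um, dz_um, dy_um = NULL, positions = NULL,
                       laterality = c("OD", "OS"), id = "volume") {
  laterality <- match.arg(laterality)
  if (length(bscans) < 1) abort("a volume needs at least one B-scan")
  dims <- vapply(bscans, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("all B-scans must share one (n_z, n_x) shape")
  }
  n <- length(bscans)
  if (is.null(positions)) {
    if (is.null(dy_um)) abort("either `positions` or `dy_um` must be given")
    positions <- tibble(x0_um = rep(0, n), y0_um = (seq_len(n) - 1) * dy_um)
  }
  positions <- as_tibble(positions)
  if (nrow(positions) != n) abort("len(positions) must equal the number of B-scans")
  ord <- order(positions$y0_um)
  bscans <- bscans[ord]
  positions <- positions[ord, , drop = FALSE]
  if (is.null(dy_um)) {
    dy_um <- if (n > 1) median(diff(positions$y0_um)) else NA_real_
  }
  if (n > 1) {
    dev <- max(abs(diff(positions$y0_um) - dy_um))
    if (dev > 1e-6) {
      warn(sprintf(paste0("B-scan spacing is not uniform (max deviation %.3g um ",
                          "from dy_um = %.6g); transverse smoothing assumes a ",
                          "constant spacing"), dev, dy_um))
    }
  }
  if (!isTRUE(dx_um > 0) || !isTRUE(dz_um > 0) || !(is.na(dy_um) || dy_um > 0)) {
    abort("pixel pitches dx_um, dz_um, dy_um must be positive")
  }
  structure(
    list(bscans = bscans, dx_um = dx_um, dz_um = dz_um, dy_um = dy_um,
         positions = positions, laterality = laterality, id = id),
    class = "oct_volume"
  )
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$bscans[[1]])
  cat(sprintf(
    "<oct_volume> '%s': %d B-scans of %d (z) x %d (x) px, %s\n  dx = %.3f um, dz = %.3f um, dy = %.3f um\n",
    x$id, length(x$bscans), d[1], d[2], x$laterality, x$dx_um, x$dz_um, x$dy_um))
  invisible(x)
}

#' @export
dim.oct_volume <- function(x) {
  c(dim(x$bscans[[1]]), length(x$bscans))
}

n_bscans <- function(vol) length(vol$bscans)

#' Load a standardized OCT volume from image files
#'
#' Reads a directory of grayscale PNG or TIFF B-scans plus a plain-text
#' metadata file, validates the stack, and rescales every B-scan to
#' `[0, 255]` (observed minimum to 0, maximum to 255; a constant image maps
#' to 0). The metadata file is a human-readable `key: value` format with a
#' global header (`dx_um`, `dz_um`, `laterality`, optional `id`) followed by
#' one `file: NAME  x0_um: X  y0_um: Y` record per B-scan (whitespace
#' separated keys on one line, or one key per line separated by blank
#' lines). B-scans are sorted by ascending `y0_um`.
#'
#' @param image_dir Directory containing the B-scan images.
#' @param metadata Path to the metadata file (default
#'   `file.path(image_dir, "volume_meta.txt")`).
#' @return An [oct_volume()].
#' @export
read_oct_volume <- function(image_dir,
                            metadata = file.path(image_dir, "volume_meta.txt")) {
  if (!dir.exists(image_dir)) abort(sprintf("image directory '%s' not found", image_dir))
  if (!file.exists(metadata)) abort(sprintf("metadata file '%s' not found", metadata))
  meta <- parse_volume_metadata(metadata)
  n <- nrow(meta$records)
  bscans <- vector("list", n)
  for (i in seq_len(n)) {
    f <- file.path(image_dir, meta$records$file[i])
    if (!file.exists(f)) abort(sprintf("B-scan image '%s' listed in metadata is missing", f))
    m <- tryCatch(read_gray_image(f), error = function(e) {
      abort(sprintf("cannot read B-scan image '%s': %s", f, conditionMessage(e)))
    })
    bscans[[i]] <- rescale_255(m)
  }
  dims <- vapply(bscans, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("B-scans do not share one shape; check the exported images")
  }
  oct_volume(bscans, dx_um = meta$header$dx_um, dz_um = meta$header$dz_um,
             positions = meta$records[, c("x0_um", "y0_um")],
             laterality = meta$header$laterality,
             id = meta$header$id %||% basename(image_dir))
}

parse_volume_metadata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  # split "key: value" pairs; several pairs may share a line
  pairs <- list()
  for (ln in lines) {
    toks <- regmatches(ln, gregexpr("[A-Za-z0-9_]+\\s*:\\s*\\S+", ln, perl = TRUE))[[1]]
    if (length(toks) == 0) abort(sprintf("cannot parse metadata line: '%s'", ln))
    for (tk in toks) {
      kv <- strsplit(tk, "\\s*:\\s*")[[1]]
      pairs[[length(pairs) + 1L]] <- c(kv[1], kv[2])
    }
  }
  keys <- vapply(pairs, `[`, "", 1)
  vals <- vapply(pairs, `[`, "", 2)
  known <- c("dx_um", "dz_um", "laterality", "id", "file", "x0_um", "y0_um")
  if (any(!keys %in% known)) {
    abort(sprintf("unknown metadata key(s): %s",
                  paste(unique(setdiff(keys, known)), collapse = ", ")))
  }
  grab1 <- function(k, required = TRUE) {
    v <- vals[keys == k]
    if (length(v) == 0) {
      if (required) abort(sprintf("metadata is missing required key '%s'", k))
      return(NULL)
    }
    v[1]
  }
  header <- list(
    dx_um = as.numeric(grab1("dx_um")),
    dz_um = as.numeric(grab1("dz_um")),
    laterality = grab1("laterality"),
    id = grab1("id", required = FALSE)
  )
  files <- vals[keys == "file"]
  x0 <- as.numeric(vals[keys == "x0_um"])
  y0 <- as.numeric(vals[keys == "y0_um"])
  if (length(files) == 0) abort("metadata lists no B-scan records")
  if (length(x0) != length(files) || length(y0) != length(files)) {
    abort(sprintf("metadata record mismatch: %d file(s) but %d x0_um / %d y0_um entries",
                  length(files), length(x0), length(y0)))
  }
  list(header = header,
       records = tibble(file = files, x0_um = x0, y0_um = y0))
}

read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("unsupported image extension '%s' (PNG or TIFF expected)", ext))
  )
  if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE], c(1, 2), mean)
  matrix(as.numeric(a), nrow = nrow(a), ncol = ncol(a))
}

#' Write an OCT volume as an image directory plus metadata
#'
#' Companion to [read_oct_volume()]. B-scans are written as 32-bit float
#' TIFF files (intensity divided by 255 so values sit in `[0, 1]`), which
#' round-trips the stored intensities exactly; scales and positions
#' round-trip through the text metadata at full printed precision.
#'
#' @param vol An [oct_volume()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
write_oct_volume <- function(vol, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  n <- n_bscans(vol)
  files <- sprintf("bscan_%03d.tiff", seq_len(n) - 1L)
  for (i in seq_len(n)) {
    tiff::writeTIFF(vol$bscans[[i]] / 255, file.path(out_dir, files[i]),
                    bits.per.sample = 32L)
  }
  hdr <- c(
    sprintf("id: %s", vol$id),
    sprintf("dx_um: %.10g", vol$dx_um),
    sprintf("dz_um: %.10g", vol$dz_um),
    sprintf("laterality: %s", vol$laterality),
    ""
  )
  rec <- sprintf("file: %s  x0_um: %.10g  y0_um: %.10g",
                 files, vol$positions$x0_um, vol$positions$y0_um)
  writeLines(c(hdr, rec), file.path(out_dir, "volume_meta.txt"))
  invisible(out_dir)
}
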