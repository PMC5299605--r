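# Shared fixtures, all generated in code.

# Small phantom: full-width B-scans, few of them; cached per test file run.
small_phantom <- local({
  cache <- list()
  function(preset, n_bscans = 4L, ...) {
    key <- paste(preset, n_bscans, ...)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- generate_phantom(phantom_spec(preset, n_bscans = n_bscans, ...))
    }
    cache[[key]]
  }
})

# Phantom whose few B-scans still cover the full scan square (macula inside).
wide_phantom <- function(preset = "clean", n_bscans = 12L, ...) {
  generate_phantom(phantom_spec(preset, n_bscans = n_bscans,
                                dy_um = 7500 / n_bscans, ...))
}

# A B-scan made of one repeated column profile.
column_image <- function(profile, n_x = 8L) {
  matrix(rep(profile, n_x), nrow = length(profile), ncol = n_x)
}

# Brute-force minimum-weight path by exhaustive DFS enumeration.
enumerate_min_path <- function(nodes, edges, source, target) {
  best <- list(w = Inf, path = NULL)
  adj <- split(seq_len(nrow(edges)), edges$from)
  dfs <- function(u, w, path) {
    if (u == target) {
      if (w < best$w) best <<- list(w = w, path = path)
      return(invisible())
    }
    for (e in adj[[as.character(u)]]) {
      v <- edges$to[e]
      if (v %in% path) next
      dfs(v, w + edges$w[e], c(path, v))
    }
  }
  dfs(source, 0, source)
  best
}

# Brute-force posterior convex-hull chain: upper envelope (max z) of all
# chords between point pairs, evaluated per column.
brute_posterior_hull <- function(x, z, xout) {
  n <- length(x)
  vapply(xout, function(q) {
    best <- -Inf
    for (i in seq_len(n)) {
      if (x[i] == q) best <- max(best, z[i])
      for (j in seq_len(n)) {
        if (x[i] < q && q < x[j]) {
          t <- (q - x[i]) / (x[j] - x[i])
          best <- max(best, z[i] + t * (z[j] - z[i]))
        }
      }
    }
    best
  }, numeric(1))
}

# Flood-fill weak components over an edge list.
flood_components <- function(ids, from, to) {
  comp <- setNames(rep(0L, length(ids)), ids)
  cid <- 0L
  for (s in ids) {
    if (comp[as.character(s)] > 0L) next
    cid <- cid + 1L
    q <- s
    comp[as.character(s)] <- cid
    while (length(q)) {
      u <- q[1]; q <- q[-1]
      nb <- c(to[from == u], from[to == u])
      nb <- nb[comp[as.character(nb)] == 0L]
      comp[as.character(nb)] <- cid
      q <- c(q, unique(nb))
    }
  }
  comp
}

# Run the anterior + CSI stages on a generated phantom and collect per-layer
# deviations from the ground truth (px, in the raw image frame for BM and
# the flattened frame for CSI).
evaluate_phantom <- function(ph, csi_pars = csi_params()) {
  vol <- ph$volume
  n <- length(vol$bscans)
  ant <- lapply(vol$bscans, segment_rpe_bm)
  sm <- transverse_smooth(vol, lapply(ant, `[[`, "bm"))
  bm_err <- csi_err <- numeric(0)
  seg_ok <- logical(n)
  for (i in seq_len(n)) {
    tru <- ph$truth$traces[[i]]
    bm_err <- c(bm_err, abs(ant[[i]]$bm$z_px - tru$BM$z_px))
    bm_flat <- layer_trace(ant[[i]]$bm$z_px + sm$shifts[[i]], layer = "BM")
    segs <- trace_csi(sm$volume$bscans[[i]], bm_flat, csi_pars,
                      vol$dx_um, vol$dz_um)
    ro <- resolve_overlaps(segs, ncol(vol$bscans[[i]]))
    seg_ok[i] <- bscan_segmented(ro$kept)
    tru_flat <- tru$CSI$z_px + sm$shifts[[i]]
    ok <- ro$trace$valid
    csi_err <- c(csi_err, abs(ro$trace$z_px[ok] - tru_flat[ok]))
  }
  list(bm_median = median(bm_err, na.rm = TRUE),
       csi_median = median(csi_err, na.rm = TRUE),
       success = success_fraction(seg_ok))
}

# Trace of length n with values z at 0-based columns x, NA elsewhere.
layer_trace_at <- function(x, z, n, layer = "RPE_POST") {
  zz <- rep(NA_real_, n)
  zz[x + 1L] <- z
  layer_trace(zz, layer = layer)
}

# Total weight of a node path (test-side, independent of the package).
path_weight_of <- function(g, path) {
  if (length(path) < 2) return(0)
  w <- 0
  for (k in seq_len(length(path) - 1)) {
    sel <- g$edges$from == path[k] & g$edges$to == path[k + 1]
    stopifnot(any(sel))
    w <- w + min(g$edges$w[sel])
  }
  w
}
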