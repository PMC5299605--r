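#' Parameters for choroid-sclera interface segmentation
#'
#' @param sigma_x_px,sigma_z_px In-plane Gaussian low-pass scales (px)
#'   applied to the smoothed B-scan before node detection and the Gabor
#'   bank.
#' @param grad_thresh Minimum axial derivative (intensity/px) for a
#'   candidate node.
#' @param curv_thresh Maximum `|d2I/dz2|` (intensity/px^2) at a node
#'   ("second derivative near zero").
#' @param A_x,A_z Jump-penalty amplitudes in x and z.
#' @param T_x,T_z Jump tolerances (px): steps below the tolerance carry no
#'   penalty, and nodes farther apart than `5*T` may not connect.
#' @param alpha Penalty exponent.
#' @param gabor_angles_deg Gabor bank angles around the +z axis (degrees).
#' @param gabor_scales_um Gabor bank scales (micrometres).
#' @param A_s,A_m,A_h Segment-score coefficients (must sum to one).
#' @param w_combine Length-4 weights for the terms
#'   `(w_Euclid, w_z, w_x, w_Affin)` of the combined edge weight.
#' @param eps Guard for `1/A` and `1/height` divisions.
#' @return A list of class `csi_params`.
#' @export
csi_params <- function(sigma_x_px = 6, sigma_z_px = 2,
                       grad_thresh = 1.0, curv_thresh = 0.05,
                       A_x = 1, A_z = 1, T_x = 10, T_z = 10, alpha = 2,
                       gabor_angles_deg = seq(-20, 20, length.out = 5),
                       gabor_scales_um = c(10, 15, 20),
                       A_s = 0.4, A_m = 0.3, A_h = 0.3,
                       w_combine = c(1, 1, 1, 1), eps = 1e-6) {
  if (abs(A_s + A_m + A_h - 1) > 1e-9) abort("A_s + A_m + A_h must equal 1")
  if (grad_thresh <= 0) abort("grad_thresh must be > 0")
  if (curv_thresh <= 0) abort("curv_thresh must be > 0")
  if (length(w_combine) != 4) abort("w_combine must have 4 entries")
  structure(list(sigma_x_px = sigma_x_px, sigma_z_px = sigma_z_px,
                 grad_thresh = grad_thresh, curv_thresh = curv_thresh,
                 A_x = A_x, A_z = A_z, T_x = T_x, T_z = T_z, alpha = alpha,
                 gabor_angles_deg = gabor_angles_deg,
                 gabor_scales_um = gabor_scales_um,
                 A_s = A_s, A_m = A_m, A_h = A_h,
                 w_combine = w_combine, eps = eps),
            class = "csi_params")
}

# Odd (sine) Gabor kernel oriented toward +z after rotation by theta, built
# on physical coordinates so anisotropic pixels are handled naturally.
# Positive response marks a dark-to-bright transition along +z_theta.
gabor_kernel <- function(theta_deg, s_um, dx_um, dz_um) {
  if (s_um / dz_um < 1) {
    abort(sprintf("Gabor scale %.3g um is below one axial pixel (dz = %.3g um)",
                  s_um, dz_um))
  }
  th <- theta_deg * pi / 180
  half_um <- 3 * s_um
  rx <- max(1L, ceiling(half_um / dx_um))
  rz <- max(1L, ceiling(half_um / dz_um))
  xs <- seq(-rx, rx) * dx_um
  zs <- seq(-rz, rz) * dz_um
  X <- matrix(xs, length(zs), length(xs), byrow = TRUE)
  Z <- matrix(zs, length(zs), length(xs))
  xr <- X * cos(th) - Z * sin(th)
  zr <- X * sin(th) + Z * cos(th)
  k <- exp(-(xr^2 + zr^2) / (2 * s_um^2)) * sin(2 * pi * zr / (4 * s_um))
  k - mean(k)
}

#' Gabor edge-probability map
#'
#' Correlates the (already low-pass filtered) B-scan with a bank of odd
#' Gabor kernels at every combination of the configured angles (default
#' within \[-20, 20\] degrees of the +z axis) and scales (default 10-20
#' micrometres), takes the pixelwise maximum response, clips it at zero,
#' and normalizes by the per-B-scan maximum so that `P` lies in `[0, 1]`
#' and peaks on dark-to-bright axial transitions. A constant image yields
#' `P == 0` everywhere.
#'
#' @param bscan Numeric matrix in `[0, 255]`, low-pass filtered with
#'   `(sigma_x_px, sigma_z_px)` (done by [trace_csi()]).
#' @param params [csi_params()].
#' @param dx_um,dz_um Pixel pitches used to build the kernels.
#' @return A matrix of class `edge_probability_map`, same shape as
#'   `bscan`.
#' @export
gabor_edge_probability <- function(bscan, params = csi_params(),
                                   dx_um, dz_um) {
  kerns <- list()
  for (th in params$gabor_angles_deg) {
    for (s in params$gabor_scales_um) {
      kerns <- c(kerns, list(gabor_kernel(th, s, dx_um, dz_um)))
    }
  }
  resps <- fft_correlate_bank(bscan, kerns)
  resp <- resps[[1]]
  for (k in seq_along(resps)[-1]) resp <- pmax(resp, resps[[k]])
  resp[resp < 0] <- 0
  mx <- max(resp)
  # FFT round-off leaves ~1e-12 residues on constant images; treat as zero
  P <- if (mx > 1e-8 * max(1, max(abs(bscan)))) resp / mx
       else matrix(0, nrow(bscan), ncol(bscan))
  class(P) <- c("edge_probability_map", class(P))
  P
}

#' Detect candidate CSI nodes as axial inflexion points
#'
#' A pixel qualifies when it lies strictly posterior to the BM, its axial
#' derivative exceeds `grad_thresh` and the magnitude of its second axial
#' derivative is below `curv_thresh`. Within each column, contiguous runs
#' of qualifying pixels collapse to the single pixel with the smallest
#' `|d2I/dz2|` (the inflexion point). Each node carries the edge
#' probability at its position.
#'
#' @param bscan Low-pass filtered B-scan matrix.
#' @param bm BM [layer_trace()] in the same (flattened) frame.
#' @param P [gabor_edge_probability()] map.
#' @param params [csi_params()].
#' @return Tibble with columns `x_px`, `z_px` (0-based), `p`.
#' @export
detect_candidate_nodes <- function(bscan, bm, P, params = csi_params()) {
  g <- axial_gradient(bscan)
  h <- abs(axial_curvature(bscan))
  n_z <- nrow(bscan); n_x <- ncol(bscan)
  zmat <- matrix(seq_len(n_z) - 1L, n_z, n_x)
  bmrow <- rep(Inf, n_x)
  bmrow[bm$valid] <- bm$z_px[bm$valid]
  qual <- g > params$grad_thresh & h < params$curv_thresh &
    sweep(zmat, 2, bmrow, ">")
  out_x <- integer(0); out_z <- integer(0)
  for (x in seq_len(n_x)) {
    q <- qual[, x]
    if (!any(q)) next
    r <- rle(q)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      zz <- starts[k]:ends[k]
      zi <- zz[which.min(h[zz, x])]
      out_x <- c(out_x, x - 1L)
      out_z <- c(out_z, zi - 1L)
    }
  }
  tibble(x_px = out_x, z_px = out_z,
         p = if (length(out_x)) P[cbind(out_z + 1L, out_x + 1L)] else numeric(0))
}

#' Edge weight between two CSI nodes
#'
#' Combines the Euclidean distance, Heaviside-gated power-law jump
#' penalties in z and x, and the inverse line integral of the edge
#' probability:
#' `w = c1*sqrt(dx^2+dz^2) + c2*A_z*H(|dz|-T_z)*(|dz|/T_z)^alpha +
#'  c3*A_x*H(|dx|-T_x)*(|dx|/T_x)^alpha + c4 / max(A, eps)`
#' where `A` sums `P` over the Bresenham line from `a` to `b` and
#' `(c1..c4) = w_combine`. Nodes must be strictly left-to-right and within
#' the `5*T_x` / `5*T_z` spacing caps; otherwise `NA` is returned (no
#' edge).
#'
#' @param a,b Nodes: lists or one-row data frames with `x_px`, `z_px`.
#' @param P Edge-probability map.
#' @param params [csi_params()].
#' @return The weight, or `NA_real_` if the nodes may not connect.
#' @export
edge_weight <- function(a, b, P, params = csi_params()) {
  dx <- b$x_px - a$x_px
  dz <- b$z_px - a$z_px
  if (dx <= 0 || abs(dz) >= 5 * params$T_z || dx >= 5 * params$T_x) {
    return(NA_real_)
  }
  A <- line_prob_sum(a$x_px, a$z_px, b$x_px, b$z_px, P)
  w_euclid <- sqrt(dx^2 + dz^2)
  w_z <- params$A_z * (abs(dz) > params$T_z) * (abs(dz) / params$T_z)^params$alpha
  w_x <- params$A_x * (abs(dx) > params$T_x) * (abs(dx) / params$T_x)^params$alpha
  w_affin <- 1 / max(A, params$eps)
  sum(params$w_combine * c(w_euclid, w_z, w_x, w_affin))
}

# Sum of P over the Bresenham-style discrete line between two pixels
# (inclusive): max(|dx|, |dz|) + 1 samples with rounded coordinates.
line_prob_sum <- function(x0, z0, x1, z1, P) {
  n <- max(abs(x1 - x0), abs(z1 - z0)) + 1
  t <- if (n == 1) 0 else seq(0, 1, length.out = n)
  xs <- round(x0 + t * (x1 - x0)) + 1L
  zs <- round(z0 + t * (z1 - z0)) + 1L
  sum(P[cbind(zs, xs)])
}

# Vectorized edge construction over all admissible node pairs.
build_csi_edges <- function(nodes, P, params) {
  n <- nrow(nodes)
  if (n < 2) {
    return(tibble(from = integer(0), to = integer(0), w = numeric(0)))
  }
  ord <- order(nodes$x_px, nodes$z_px)
  nodes <- nodes[ord, , drop = FALSE]
  x <- nodes$x_px; z <- nodes$z_px
  max_dx <- 5 * params$T_x
  # candidate pairs: for each node, partners in the strictly-later columns
  # within the x window (nodes are sorted by x, ties contiguous)
  hi <- findInterval(x + max_dx - 1e-9, x)
  start <- findInterval(x, x) + 1L         # first index with larger x
  cnt <- pmax(hi - start + 1L, 0L)
  from <- rep.int(seq_len(n), cnt)
  to <- sequence(cnt, from = start)
  if (length(from) == 0) {
    return(tibble(from = integer(0), to = integer(0), w = numeric(0)))
  }
  dx <- x[to] - x[from]
  dz <- z[to] - z[from]
  keep <- dx < 5 * params$T_x & abs(dz) < 5 * params$T_z
  from <- from[keep]; to <- to[keep]; dx <- dx[keep]; dz <- dz[keep]
  if (length(from) == 0) {
    return(tibble(from = integer(0), to = integer(0), w = numeric(0)))
  }
  # line integral of P, all edges at once
  npts <- pmax(abs(dx), abs(dz)) + 1L
  eid <- rep.int(seq_along(from), npts)
  t <- sequence(npts) - 1L
  tt <- t / pmax(npts[eid] - 1L, 1L)
  xs <- round(x[from][eid] + tt * dx[eid]) + 1L
  zs <- round(z[from][eid] + tt * dz[eid]) + 1L
  A <- as.numeric(rowsum(P[cbind(zs, xs)], eid))
  w_euclid <- sqrt(dx^2 + dz^2)
  w_z <- params$A_z * (abs(dz) > params$T_z) * (abs(dz) / params$T_z)^params$alpha
  w_x <- params$A_x * (abs(dx) > params$T_x) * (abs(dx) / params$T_x)^params$alpha
  w_affin <- 1 / pmax(A, params$eps)
  c1 <- params$w_combine
  w <- c1[1] * w_euclid + c1[2] * w_z + c1[3] * w_x + c1[4] * w_affin
  list(nodes = nodes,
       edges = tibble(from = from, to = to, w = w))
}

#' Score a CSI path segment
#'
#' `W_sum` is the sum of the node edge probabilities, `W_mean` their mean,
#' and `W_height` one over the mean node depth (z, px). The score is the
#' convex combination `A_s*W_sum + A_m*W_mean + A_h*W_height`; it is
#' monotone increasing in every node's probability.
#'
#' @param nodes Tibble with `x_px`, `z_px`, `p` (non-empty).
#' @param params [csi_params()].
#' @return List with `W_sum`, `W_mean`, `W_height`, `score`.
#' @export
score_segment <- function(nodes, params = csi_params()) {
  if (nrow(nodes) == 0) abort("cannot score an empty segment")
  W_sum <- sum(nodes$p)
  W_mean <- W_sum / nrow(nodes)
  W_height <- 1 / max(mean(nodes$z_px), params$eps)
  list(W_sum = W_sum, W_mean = W_mean, W_height = W_height,
       score = params$A_s * W_sum + params$A_m * W_mean + params$A_h * W_height)
}

new_path_segment <- function(nodes, params) {
  s <- score_segment(nodes, params)
  structure(c(list(nodes = nodes), s), class = "path_segment")
}

#' @export
print.path_segment <- function(x, ...) {
  cat(sprintf("<path_segment> %d nodes, x in [%d, %d], score %.4g\n",
              nrow(x$nodes), min(x$nodes$x_px), max(x$nodes$x_px), x$score))
  invisible(x)
}

#' Trace the choroid-sclera interface on one B-scan
#'
#' Detects inflexion-point nodes posterior to the BM, builds the weighted
#' graph ([edge_weight()] semantics) with virtual endpoint nodes, and runs
#' Dijkstra. If no path spans from the first to the last occupied column,
#' the graph is decomposed into weakly connected fragments and the
#' shortest path is found within each. Returns one scored
#' [score_segment()] segment per surviving search.
#'
#' @param bscan B-scan matrix (flattened frame) in `[0, 255]`; low-pass
#'   filtering with `(sigma_x_px, sigma_z_px)` is applied here.
#' @param bm BM trace in the same frame.
#' @param params [csi_params()].
#' @param dx_um,dz_um Pixel pitches (for the Gabor bank).
#' @return List of `path_segment` objects (empty if no nodes were found).
#' @export
trace_csi <- function(bscan, bm, params = csi_params(), dx_um, dz_um) {
  sm <- gaussian_blur(bscan, params$sigma_z_px, params$sigma_x_px)
  P <- gabor_edge_probability(sm, params, dx_um, dz_um)
  nodes <- detect_candidate_nodes(sm, bm, P, params)
  if (nrow(nodes) == 0) return(list())
  ge <- build_csi_edges(nodes, P, params)
  nd <- ge$nodes
  nd$id <- seq_len(nrow(nd))
  ntab <- tibble(id = nd$id, x = nd$x_px, z = nd$z_px, virtual = FALSE)
  g <- attach_virtual_endpoints(ntab, ge$edges)
  vs <- g$nodes$id[g$nodes$virtual & g$nodes$x == -Inf]
  ve <- g$nodes$id[g$nodes$virtual & g$nodes$x == Inf]
  path <- shortest_path(g, vs, ve)
  seg_from_ids <- function(ids) {
    ids <- ids[!ids %in% c(vs, ve)]
    new_path_segment(nd[ids, c("x_px", "z_px", "p")], params)
  }
  if (!is.null(path)) {
    return(list(seg_from_ids(path)))
  }
  frags <- graph_fragments(graph_spec(ntab, ge$edges))
  segs <- list()
  for (f in frags) {
    fvs <- f$nodes$id[f$nodes$virtual & f$nodes$x == -Inf]
    fve <- f$nodes$id[f$nodes$virtual & f$nodes$x == Inf]
    p <- shortest_path(f, fvs, fve)
    if (is.null(p)) next
    ids <- p[!p %in% c(fvs, fve)]
    segs <- c(segs, list(new_path_segment(nd[ids, c("x_px", "z_px", "p")], params)))
  }
  segs
}

#' Resolve overlapping CSI segments into a single trace
#'
#' Greedy by descending score: a segment is kept iff its x-interval shares
#' no column with the already-kept segments. Surviving nodes are merged and
#' sorted by x; columns between nodes stay invalid (no interpolation at
#' this stage).
#'
#' @param segments List of `path_segment`s.
#' @param n_x Number of image columns for the output trace.
#' @return List with `trace` (a CSI [layer_trace()]), `kept` (the surviving
#'   segments) and `nodes` (merged node tibble with probabilities).
#' @export
resolve_overlaps <- function(segments, n_x) {
  if (length(segments) == 0) {
    return(list(trace = layer_trace(rep(NA_real_, n_x), layer = "CSI"),
                kept = list(), nodes = tibble(x_px = integer(0), z_px = numeric(0),
                                              p = numeric(0))))
  }
  scores <- vapply(segments, function(s) s$score, numeric(1))
  lefts <- vapply(segments, function(s) min(s$nodes$x_px), numeric(1))
  ord <- order(-scores, lefts, vapply(segments, function(s) nrow(s$nodes), numeric(1)))
  occupied <- rep(FALSE, n_x)
  kept <- list()
  for (i in ord) {
    s <- segments[[i]]
    span <- (min(s$nodes$x_px):max(s$nodes$x_px)) + 1L
    if (any(occupied[span])) next
    occupied[span] <- TRUE
    kept <- c(kept, list(s))
  }
  nodes <- dplyr::arrange(dplyr::bind_rows(lapply(kept, `[[`, "nodes")), .data$x_px)
  z <- rep(NA_real_, n_x)
  p <- rep(NA_real_, n_x)
  z[nodes$x_px + 1L] <- nodes$z_px
  p[nodes$x_px + 1L] <- nodes$p
  tr <- layer_trace(z, layer = "CSI")
  list(trace = tr, kept = kept, nodes = nodes)
}

#' Was a B-scan successfully segmented?
#'
#' A B-scan counts as successfully segmented when at least one kept CSI
#' segment contains at least 4 nodes.
#'
#' @param segments List of kept `path_segment`s.
#' @return Logical scalar.
#' @export
bscan_segmented <- function(segments) {
  any(vapply(segments, function(s) nrow(s$nodes) >= 4L, logical(1)))
}
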