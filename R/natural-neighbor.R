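# Sibson natural-neighbor interpolation on scattered 2-D data.
#
# The Delaunay triangulation is computed once with deldir; each query point
# is interpolated by the Bowyer-Watson "stolen area" construction: the
# triangles whose circumcircles contain the query form the insertion
# cavity, and the Sibson coordinate of each cavity vertex is the area its
# Voronoi cell would lose if the query were inserted. Exact at data sites
# and reproduces linear fields exactly (Sibson's linear precision).

circumcenter <- function(ax, ay, bx, by, cx, cy) {
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  cbind(ux, uy)
}

shoelace_area <- function(px, py) {
  n <- length(px)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(px * py[j] - px[j] * py)) / 2
}

point_in_hull <- function(qx, qy, hx, hy, tol = 0) {
  # hull vertices counterclockwise; inside if never strictly right of an edge
  n <- length(hx)
  j <- c(2:n, 1)
  cr <- (hx[j] - hx) * (qy - hy) - (hy[j] - hy) * (qx - hx)
  all(cr >= -tol)
}

# Build the triangulation state used by nn_interpolate queries.
nn_triangulation <- function(x, y, v) {
  n <- length(x)
  if (n < 3) abort("natural-neighbor interpolation needs at least 3 points")
  rngx <- diff(range(x)); rngy <- diff(range(y))
  diag <- sqrt(rngx^2 + rngy^2)
  if (diag == 0) abort("degenerate point geometry; provide denser, non-coincident sampling")
  sv <- svd(cbind(x - mean(x), y - mean(y)), nu = 0, nv = 0)$d
  if (sv[2] < 1e-9 * diag) {
    abort("degenerate (collinear) point geometry; natural-neighbor interpolation needs denser, non-collinear sampling")
  }
  # deterministic sub-resolution jitter breaks the cocircular degeneracies of
  # gridded sites without touching the RNG state; the induced value error is
  # bounded by the field gradient times ~1e-6 of the point-set diameter
  jit <- function(i, salt, amp) {
    u <- ((i * 2654435761 + salt * 97911) %% 65536) / 65536
    (u - 0.5) * amp * diag
  }
  tl <- NULL
  for (amp in c(1e-6, 1e-5, 1e-4)) {
    xj <- x + jit(seq_len(n), 1, amp)
    yj <- y + jit(seq_len(n), 2, amp)
    tl <- tryCatch({
      res <- NULL
      utils::capture.output(utils::capture.output({
        dd <- deldir::deldir(xj, yj, suppressMsge = TRUE)
        res <- deldir::triang.list(dd)
      }, type = "message"), type = "output")
      res
    }, error = function(e) NULL)
    if (!is.null(tl) && length(tl) > 0) break
  }
  if (is.null(tl) || length(tl) == 0) {
    abort("degenerate (collinear) point geometry; natural-neighbor interpolation needs non-collinear points")
  }
  tri <- t(vapply(tl, function(tt) tt$ptNum, integer(3)))
  cc <- circumcenter(xj[tri[, 1]], yj[tri[, 1]], xj[tri[, 2]], yj[tri[, 2]],
                     xj[tri[, 3]], yj[tri[, 3]])
  r2 <- (xj[tri[, 1]] - cc[, 1])^2 + (yj[tri[, 1]] - cc[, 2])^2
  hull <- grDevices::chull(xj, yj)
  hull <- rev(hull)  # chull returns clockwise; we want counterclockwise
  list(x = xj, y = yj, v = v, x0 = x, y0 = y, tri = tri,
       ccx = cc[, 1], ccy = cc[, 2], r2 = r2,
       hx = xj[hull], hy = yj[hull], diag = diag)
}

# Sibson weights for one query point; returns NULL outside the hull.
sibson_weights <- function(st, qx, qy) {
  if (!point_in_hull(qx, qy, st$hx, st$hy, tol = 1e-9 * st$diag^2)) return(NULL)
  d2 <- (qx - st$ccx)^2 + (qy - st$ccy)^2
  cav <- which(d2 < st$r2 * (1 - 1e-12))
  if (length(cav) == 0) {
    cav <- which(d2 < st$r2 * (1 + 1e-9))
    if (length(cav) == 0) return(NULL)
  }
  tris <- st$tri[cav, , drop = FALSE]
  # boundary edges: undirected edges appearing in exactly one cavity triangle
  ed <- rbind(tris[, c(1, 2), drop = FALSE], tris[, c(2, 3), drop = FALSE],
              tris[, c(3, 1), drop = FALSE])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(key)
  bnd <- ed[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
  if (nrow(bnd) < 3) return(NULL)
  # orient each boundary edge counterclockwise around q, then chain them
  crs <- (st$x[bnd[, 1]] - qx) * (st$y[bnd[, 2]] - qy) -
         (st$y[bnd[, 1]] - qy) * (st$x[bnd[, 2]] - qx)
  flip <- crs < 0
  bnd[flip, ] <- bnd[flip, c(2, 1), drop = FALSE]
  if (anyDuplicated(bnd[, 1]) || anyDuplicated(bnd[, 2])) return(NULL)
  nxt <- setNames(bnd[, 2], as.character(bnd[, 1]))
  m <- nrow(bnd)
  poly <- integer(m)
  poly[1] <- bnd[1, 1]
  for (k in 2:m) {
    nv <- nxt[as.character(poly[k - 1])]
    if (is.na(nv)) return(NULL)
    poly[k] <- nv
  }
  last <- nxt[as.character(poly[m])]
  if (is.na(last) || last != poly[1]) return(NULL)

  # circumcenters of the new triangles (q, v_k, v_{k+1})
  nxt_i <- c(2:m, 1)
  u <- circumcenter(rep(qx, m), rep(qy, m), st$x[poly], st$y[poly],
                    st$x[poly[nxt_i]], st$y[poly[nxt_i]])
  # cavity-triangle adjacency and per-vertex membership
  w <- numeric(m)
  prev_i <- c(m, seq_len(m - 1))
  for (k in seq_len(m)) {
    v <- poly[k]
    vprev <- poly[prev_i[k]]
    vnext <- poly[nxt_i[k]]
    inc <- which(tris[, 1] == v | tris[, 2] == v | tris[, 3] == v)
    # walk the incident cavity triangles from the (vprev, v) edge to (v, vnext)
    cur <- inc[apply(tris[inc, , drop = FALSE], 1, function(tt) vprev %in% tt)]
    chain <- integer(0)
    guard <- 0L
    other <- vprev
    repeat {
      guard <- guard + 1L
      if (length(cur) == 0 || guard > length(inc) + 2L) return(NULL)
      cur <- cur[1]
      chain <- c(chain, cur)
      tt <- tris[cur, ]
      third <- setdiff(tt, c(v, other))
      if (length(third) != 1) return(NULL)
      if (third == vnext) break
      nxt_tri <- setdiff(inc[apply(tris[inc, , drop = FALSE], 1,
                                   function(t2) third %in% t2)], chain)
      other <- third
      cur <- nxt_tri
    }
    px <- c(u[prev_i[k], 1], st$ccx[cav][chain], u[k, 1])
    py <- c(u[prev_i[k], 2], st$ccy[cav][chain], u[k, 2])
    w[k] <- shoelace_area(px, py)
  }
  if (!all(is.finite(w)) || sum(w) <= 0) return(NULL)
  w <- w / sum(w)
  # Sibson coordinates are local coordinates: they must reproduce the query
  # position itself; reject numerically broken cavities
  if (abs(sum(w * st$x[poly]) - qx) > 1e-6 * st$diag ||
      abs(sum(w * st$y[poly]) - qy) > 1e-6 * st$diag) {
    return(NULL)
  }
  list(idx = poly, w = w)
}

# Barycentric weights within the Delaunay triangle containing q; linear
# precision fallback for degenerate cavity geometries.
barycentric_weights <- function(st, qx, qy) {
  x1 <- st$x[st$tri[, 1]]; y1 <- st$y[st$tri[, 1]]
  x2 <- st$x[st$tri[, 2]]; y2 <- st$y[st$tri[, 2]]
  x3 <- st$x[st$tri[, 3]]; y3 <- st$y[st$tri[, 3]]
  den <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  l1 <- ((y2 - y3) * (qx - x3) + (x3 - x2) * (qy - y3)) / den
  l2 <- ((y3 - y1) * (qx - x3) + (x1 - x3) * (qy - y3)) / den
  l3 <- 1 - l1 - l2
  tol <- -1e-9
  hit <- which(l1 >= tol & l2 >= tol & l3 >= tol)
  if (length(hit) == 0) return(NULL)
  k <- hit[1]
  list(idx = st$tri[k, ], w = pmax(c(l1[k], l2[k], l3[k]), 0))
}

#' Sibson natural-neighbor interpolation of scattered values
#'
#' Interpolates `(x, y, v)` samples at query locations. Queries that
#' coincide with a data site (within `1e-9` of the point-set diameter)
#' return the site value exactly; queries outside the convex hull of the
#' sites return `NA`. The interpolant has Sibson's linear precision: data
#' drawn from a plane `a*x + b*y + c` are reproduced exactly inside the
#' hull.
#'
#' @param x,y,v Numeric vectors: site coordinates and values.
#' @param xout,yout Query coordinates (same length).
#' @return Numeric vector of interpolated values (`NA` outside the hull).
#' @export
nn_interpolate <- function(x, y, v, xout, yout) {
  ok <- is.finite(x) & is.finite(y) & is.finite(v)
  st <- nn_triangulation(x[ok], y[ok], v[ok])
  out <- rep(NA_real_, length(xout))
  jq <- function(i, salt) {
    u <- ((i * 40503 + salt * 8191) %% 65536) / 65536
    (u - 0.5) * 2e-8 * st$diag
  }
  site <- match(paste(xout, yout), paste(st$x0, st$y0))
  for (q in seq_along(xout)) {
    if (!is.na(site[q])) {
      out[q] <- st$v[site[q]]
      next
    }
    # nudge queries off exact Voronoi-vertex degeneracies (sub-resolution)
    qx <- xout[q] + jq(q, 1)
    qy <- yout[q] + jq(q, 2)
    sw <- sibson_weights(st, qx, qy)
    if (is.null(sw)) sw <- barycentric_weights(st, qx, qy)
    if (!is.null(sw)) out[q] <- sum(sw$w * st$v[sw$idx])
  }
  out
}
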