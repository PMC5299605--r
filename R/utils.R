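#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats median approx dnorm lm coef fitted setNames quantile sd var spline IQR
#' @importFrom utils head tail modifyList
NULL

# Rescale intensities so observed min -> 0, max -> 255; constant input -> 0.
rescale_255 <- function(m) {
  rng <- range(m, finite = TRUE)
  if (!all(is.finite(rng))) abort("image contains no finite intensities")
  if (rng[2] - rng[1] <= 0) {
    m[] <- 0
    return(m)
  }
  (m - rng[1]) / (rng[2] - rng[1]) * 255
}

# Separable Gaussian low-pass on a matrix (rows = z, cols = x), replicate edges.
gaussian_blur <- function(m, sigma_z = 0, sigma_x = sigma_z) {
  blur1 <- function(mat, sigma, along_rows) {
    if (sigma <= 0) return(mat)
    r <- max(1L, ceiling(3 * sigma))
    k <- dnorm(seq(-r, r), sd = sigma)
    k <- k / sum(k)
    n <- if (along_rows) nrow(mat) else ncol(mat)
    idx <- outer(seq_len(n), seq(-r, r), "+")
    idx[idx < 1L] <- 1L
    idx[idx > n] <- n
    if (along_rows) {
      out <- matrix(0, nrow(mat), ncol(mat))
      for (j in seq_len(2L * r + 1L)) out <- out + k[j] * mat[idx[, j], , drop = FALSE]
    } else {
      out <- matrix(0, nrow(mat), ncol(mat))
      for (j in seq_len(2L * r + 1L)) out <- out + k[j] * mat[, idx[, j], drop = FALSE]
    }
    out
  }
  m <- blur1(m, sigma_z, along_rows = TRUE)
  blur1(m, sigma_x, along_rows = FALSE)
}

# Central-difference first derivative along z (rows); one-sided at the edges.
axial_gradient <- function(m) {
  n <- nrow(m)
  g <- matrix(0, n, ncol(m))
  g[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / 2
  g[1, ] <- m[2, ] - m[1, ]
  g[n, ] <- m[n, ] - m[n - 1, ]
  g
}

# Second derivative along z.
axial_curvature <- function(m) {
  n <- nrow(m)
  h <- matrix(0, n, ncol(m))
  h[2:(n - 1), ] <- m[3:n, ] - 2 * m[2:(n - 1), ] + m[1:(n - 2), ]
  h[1, ] <- h[2, ]
  h[n, ] <- h[n - 1, ]
  h
}

# Linear interpolation filling of a numeric vector with NAs; edges extended
# with the nearest finite value.
fill_linear <- function(z) {
  ok <- is.finite(z)
  if (!any(ok)) return(z)
  if (sum(ok) == 1L) {
    z[] <- z[ok]
    return(z)
  }
  x <- seq_along(z)
  approx(x[ok], z[ok], xout = x, rule = 2)$y
}

# Correlate one image with a bank of odd-dimension kernels sharing a single
# padded-image FFT (replicate boundary). Equivalent to per-kernel direct
# correlation; exact up to FFT round-off.
fft_correlate_bank <- function(img, kernels) {
  nz <- nrow(img); nx <- ncol(img)
  rz <- max(vapply(kernels, function(k) (nrow(k) - 1L) %/% 2L, integer(1)))
  rx <- max(vapply(kernels, function(k) (ncol(k) - 1L) %/% 2L, integer(1)))
  zi <- pmin(pmax(seq_len(nz + 2L * rz) - rz, 1L), nz)
  xi <- pmin(pmax(seq_len(nx + 2L * rx) - rx, 1L), nx)
  pad <- img[zi, xi, drop = FALSE]
  Pz <- nrow(pad); Px <- ncol(pad)
  Fimg <- stats::fft(pad)
  lapply(kernels, function(k) {
    kz <- nrow(k); kx <- ncol(k)
    cz <- (kz + 1L) %/% 2L; cx <- (kx + 1L) %/% 2L
    K <- matrix(0, Pz, Px)
    # embed with the kernel center wrapped to (1, 1)
    zidx <- ((seq_len(kz) - cz) %% Pz) + 1L
    xidx <- ((seq_len(kx) - cx) %% Px) + 1L
    K[zidx, xidx] <- k
    out <- Re(stats::fft(Fimg * Conj(stats::fft(K)), inverse = TRUE)) / (Pz * Px)
    out[(rz + 1L):(rz + nz), (rx + 1L):(rx + nx), drop = FALSE]
  })
}

# Gaussian smoothing of a 1-D series (replicate edges).
smooth_vec <- function(z, sigma) {
  if (sigma <= 0 || length(z) < 3) return(z)
  matrix(gaussian_blur(matrix(z, ncol = 1), sigma_z = sigma, sigma_x = 0),
         ncol = 1)[, 1]
}
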