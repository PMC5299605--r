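test_that("gradient peaks match a 1-D brute-force oracle on a toy column", {
  prof <- c(0, 0, 200, 200, 0, 0, 180, 180, 0, 0)
  img <- column_image(prof, n_x = 8L)
  pars <- rpe_bm_params(sigma_pre_px = 0.4)
  det <- detect_rvi_rpe(img, pars)
  # independent oracle: local maxima of the central-difference gradient of
  # the same smoothed profile, two largest, sorted anterior-first
  n <- length(prof)
  sm <- choroidseg:::gaussian_blur(img, 0.4, 0.4)[, 1]
  g <- c(sm[2] - sm[1], (sm[3:n] - sm[1:(n - 2)]) / 2, sm[n] - sm[n - 1])
  loc <- which(g[2:(n - 1)] > g[1:(n - 2)] & g[2:(n - 1)] >= g[3:n] &
                 g[2:(n - 1)] > 0) + 1L
  top2 <- sort(loc[order(g[loc], decreasing = TRUE)][1:2])
  expect_equal(det$rvi$z_px[1], top2[1] - 1)
  expect_equal(det$rpe_ant$z_px[1], top2[2] - 1)
  expect_true(all(det$rvi$z_px < det$rpe_ant$z_px))
  expect_true(all(det$rpe_ant$z_px <= det$rpe_post_est$z_px))
})

test_that("a constant image fails RVI/RPE detection with an error", {
  expect_error(detect_rvi_rpe(matrix(100, 40, 10)), "failed")
})

test_that("detection on the clean phantom lands within a pixel of the truth", {
  ph <- small_phantom("clean", 2L)
  b <- ph$volume$bscans[[1]]
  tru <- ph$truth$traces[[1]]
  det <- detect_rvi_rpe(b)
  ok <- det$rvi$valid
  expect_gt(mean(ok), 0.9)
  expect_lt(median(abs(det$rvi$z_px[ok] - tru$RVI$z_px[ok])), 1.5)
  spec <- phantom_spec("clean")
  band_px <- spec$rpe_band_um / spec$dz_um
  expect_lt(median(abs(det$rpe_ant$z_px[ok] - (tru$BM$z_px[ok] - band_px))), 1.5)
})

test_that("outlier rejection is single-pass and restores spikes by interpolation", {
  x <- 0:60
  z <- 100 + 0.001 * (x - 30)^2          # exactly a low-order polynomial
  tr <- layer_trace(z, layer = "RPE_POST")
  expect_equal(reject_outliers(tr)$z_px, z, tolerance = 1e-6)

  z2 <- z
  z2[31] <- z[31] + 500                  # one gross spike
  out <- reject_outliers(layer_trace(z2, layer = "RPE_POST"))
  expect_equal(out$z_px[31], (z2[30] + z2[32]) / 2, tolerance = 1e-6)

  z3 <- z
  z3[20:21] <- z[20:21] + 300            # two adjacent spikes, one pass
  out3 <- reject_outliers(layer_trace(z3, layer = "RPE_POST"))
  expect_equal(out3$z_px[20], z[19] + (z[22] - z[19]) / 3, tolerance = 1e-6)
  expect_equal(out3$z_px[21], z[19] + 2 * (z[22] - z[19]) / 3, tolerance = 1e-6)

  # never increases the worst residual against the polynomial fit
  fit <- lm(z3 ~ poly(x, 5, raw = TRUE))
  expect_lte(max(abs(out3$z_px - fitted(fit))), max(abs(z3 - fitted(fit))))
})

test_that("outlier rejection passes through short traces with a warning", {
  tr <- layer_trace(c(1, 2, 3, NA, NA), c(TRUE, TRUE, TRUE, FALSE, FALSE),
                    layer = "RVI")
  expect_warning(out <- reject_outliers(tr), "too few")
  expect_equal(out$z_px[1:3], c(1, 2, 3))
})

test_that("RPE-center refinement follows the brightest ridge", {
  img <- matrix(0, 30, 10)
  img[14, ] <- 255                        # single bright row inside the band
  ant <- layer_trace(rep(8, 10), layer = "RPE_CENTER")
  post <- layer_trace(rep(20, 10), layer = "RPE_POST")
  ctr <- refine_rpe_center(img, ant, post)
  expect_equal(ctr$z_px, rep(13, 10))

  # 3-column toy band: exhaustive enumeration over all columnwise paths
  band <- matrix(c(10, 200, 30,
                   240, 20, 50,
                   30, 180, 220), nrow = 3, byrow = FALSE)
  img2 <- matrix(0, 7, 3)
  img2[3:5, ] <- band
  a2 <- layer_trace(rep(2, 3), layer = "RPE_CENTER")
  p2 <- layer_trace(rep(4, 3), layer = "RPE_POST")
  got <- refine_rpe_center(img2, a2, p2, rpe_bm_params(step_cap_px = 2))
  paths <- expand.grid(z1 = 2:4, z2 = 2:4, z3 = 2:4)
  paths <- paths[abs(paths$z2 - paths$z1) <= 2 & abs(paths$z3 - paths$z2) <= 2, ]
  costs <- apply(paths, 1, function(p) sum(255 - img2[cbind(p + 1, 1:3)]))
  expect_equal(sum(255 - img2[cbind(got$z_px + 1, 1:3)]), min(costs))

  # uniform band: flattest admissible path
  img3 <- matrix(100, 20, 6)
  a3 <- layer_trace(rep(5, 6), layer = "RPE_CENTER")
  p3 <- layer_trace(rep(12, 6), layer = "RPE_POST")
  flat <- refine_rpe_center(img3, a3, p3)
  expect_equal(diff(flat$z_px), rep(0, 5))
})

test_that("the posterior shift recovers half the band thickness on the phantom", {
  spec <- phantom_spec("clean", n_bscans = 2L)
  ph <- small_phantom("clean", 2L)
  seg <- segment_rpe_bm(ph$volume$bscans[[1]])
  band_px <- spec$rpe_band_um / spec$dz_um
  expect_lt(abs(seg$shift_px - band_px / 2), 1)
})

test_that("a flat posterior band falls back to the default shift with a warning", {
  img <- matrix(100, 40, 8)
  ctr <- layer_trace(rep(10, 8), layer = "RPE_CENTER")
  expect_warning(res <- locate_posterior_rpe(img, ctr), "default shift")
  expect_equal(res$shift_px, rpe_bm_params()$default_shift_px)
})

test_that("the convex-hull BM bridges drusen and fixes convex traces", {
  x <- 0:40
  # posterior-dome trace (concave toward the posterior): hull fixed point
  dome <- 100 + 20 * (1 - ((x - 20) / 20)^2)
  tr <- layer_trace(dome, layer = "RPE_POST")
  expect_equal(bm_from_convex_hull(tr)$z_px, dome, tolerance = 1e-6)

  # an anterior drusen bump is bridged by a straight chord
  bumped <- dome
  bumped[15:25] <- bumped[15:25] - 15
  trb <- layer_trace(bumped, layer = "RPE_POST")
  bm <- bm_from_convex_hull(trb)
  oracle <- brute_posterior_hull(x, bumped, x)
  expect_equal(bm$z_px, oracle, tolerance = 1e-9)
  expect_true(all(bm$z_px >= bumped - 1e-9))

  # a straight line maps to itself, and the hull is idempotent
  line <- layer_trace(5 + 0.3 * x, layer = "RPE_POST")
  expect_equal(bm_from_convex_hull(line)$z_px, 5 + 0.3 * x, tolerance = 1e-9)
  twice <- bm_from_convex_hull(bm_from_convex_hull(trb))
  expect_equal(twice$z_px, bm$z_px, tolerance = 1e-9)

  expect_error(bm_from_convex_hull(layer_trace(c(1, 2, NA, NA),
                                               c(TRUE, TRUE, FALSE, FALSE),
                                               layer = "RPE_POST")),
               "3 valid")
})

test_that("hull BM matches the brute-force hull on random traces", {
  set.seed(42)
  for (k in 1:25) {
    n <- sample(8:25, 1)
    x <- sort(sample(0:60, n))
    z <- 50 + cumsum(rnorm(n, 0, 3))
    bm <- bm_from_convex_hull(layer_trace_at(x, z, 61))
    oracle <- brute_posterior_hull(x, z, x)
    got <- bm$z_px[x + 1]
    expect_equal(got, oracle, tolerance = 1e-9)
  }
})

test_that("drusen preset: hull BM beats the raw posterior RPE under drusen", {
  spec <- phantom_spec("drusen", n_bscans = 12L, dy_um = 7500 / 12)
  ph <- generate_phantom(spec)
  vol <- ph$volume
  i <- 5L   # B-scan crossing two drusen
  seg <- segment_rpe_bm(vol$bscans[[i]])
  tru <- ph$truth$traces[[i]]$BM
  y_um <- (i - 0.5) * spec$dy_um
  x_um <- (seq_len(spec$n_x) - 0.5) * spec$dx_um
  under <- rep(FALSE, spec$n_x)
  for (k in seq_len(nrow(spec$drusen))) {
    d <- spec$drusen[k, ]
    under <- under | ((x_um - d$cx_um)^2 + (y_um - d$cy_um)^2 < (0.8 * d$r_um)^2)
  }
  expect_gt(sum(under), 10)
  dev_bm <- median(abs(seg$bm$z_px[under] - tru$z_px[under]))
  dev_post <- median(abs(seg$rpe_post$z_px[under] - tru$z_px[under]))
  expect_lte(dev_bm, dev_post)
})
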