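ph_scales <- function() {
  spec <- phantom_spec("clean")
  c(dx = spec$dx_um, dz = spec$dz_um)
}

test_that("edge probability is normalized and peaks on dark-to-bright steps", {
  sc <- ph_scales()
  # constant image -> P identically zero
  P0 <- gabor_edge_probability(matrix(100, 80, 30), csi_params(),
                               sc["dx"], sc["dz"])
  expect_true(all(P0 == 0))

  # horizontal dark -> bright step
  img <- matrix(50, 120, 40)
  img[70:120, ] <- 200
  P <- gabor_edge_probability(img, csi_params(), sc["dx"], sc["dz"])
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(max(P), 1)
  peaks <- apply(P[, 5:35], 2, which.max)
  expect_true(all(abs(peaks - 69.5) <= 1.5))

  # a bright -> dark step: the (side-lobe) response is displaced off the
  # step row, unlike the dark -> bright case which peaks on it
  img2 <- matrix(200, 120, 40)
  img2[70:120, ] <- 50
  P2 <- gabor_edge_probability(img2, csi_params(), sc["dx"], sc["dz"])
  peaks2 <- apply(P2[, 5:35], 2, which.max)
  expect_true(all(abs(peaks2 - 69.5) > 4))
})

test_that("Gabor scales below one axial pixel are rejected", {
  expect_error(gabor_edge_probability(matrix(0, 10, 10), csi_params(),
                                      dx_um = 10, dz_um = 12),
               "below one axial pixel")
})

test_that("candidate nodes sit on inflexion points posterior to the BM", {
  pars <- csi_params()
  bm0 <- layer_trace(rep(0, 30), layer = "BM")
  expect_equal(nrow(detect_candidate_nodes(matrix(7, 60, 30), bm0,
                                           matrix(0, 60, 30), pars)), 0)

  # single sigmoid transition in one column: exactly one node at the midpoint
  z <- 0:99
  prof <- 50 + 150 * plogis((z - 60) / 3)
  img <- matrix(50, 100, 9)
  img[, 5] <- prof
  bm <- layer_trace(rep(10, 9), layer = "BM")
  P <- matrix(0.5, 100, 9)
  nodes <- detect_candidate_nodes(img, bm, P, pars)
  expect_equal(nrow(nodes), 1)
  expect_equal(nodes$x_px, 4)
  expect_lt(abs(nodes$z_px - 60), 1 + 1e-9)
  expect_equal(nodes$p, 0.5)

  # nothing anterior to the BM qualifies even with a strong gradient
  bm_deep <- layer_trace(rep(80, 9), layer = "BM")
  expect_equal(nrow(detect_candidate_nodes(img, bm_deep, P, pars)), 0)
})

test_that("phantom vessels produce nodes on posterior rims only", {
  ph <- small_phantom("clean", 2L)
  spec <- phantom_spec("clean")
  b <- ph$volume$bscans[[1]]
  pars <- csi_params()
  sm <- choroidseg:::gaussian_blur(b, pars$sigma_z_px, pars$sigma_x_px)
  P <- gabor_edge_probability(sm, pars, spec$dx_um, spec$dz_um)
  tru <- ph$truth$traces[[1]]
  bm <- tru$BM
  nodes <- detect_candidate_nodes(sm, bm, P, pars)
  expect_gt(nrow(nodes), 50)
  csi_z <- tru$CSI$z_px[nodes$x_px + 1]
  # nodes cluster at the CSI (vessel posterior rims / sclera onset), with
  # none on the anterior vessel walls well above it
  expect_gt(mean(abs(nodes$z_px - csi_z) < 6), 0.85)
  expect_lt(mean(nodes$z_px < csi_z - 12), 0.05)
})

test_that("edge weights follow the gated penalty formula to 1e-9", {
  pars <- csi_params(A_x = 2, A_z = 3, T_x = 4, T_z = 5, alpha = 2,
                     w_combine = c(0.7, 1.2, 0.9, 1.5))
  P <- matrix(1, 50, 50)
  a <- list(x_px = 10, z_px = 20)

  # inside both tolerances the Heaviside gates close
  b1 <- list(x_px = 13, z_px = 22)
  w1 <- edge_weight(a, b1, P, pars)
  expect_equal(w1, 0.7 * sqrt(9 + 4) + 1.5 * (1 / 4), tolerance = 1e-9)

  # P == 1 along a straight 5-pixel line: affinity sum is 5
  b2 <- list(x_px = 14, z_px = 20)
  w2 <- edge_weight(a, b2, P, pars)
  expect_equal(w2, 0.7 * 4 + 1.5 / 5, tolerance = 1e-9)

  # both penalties open: direct formula evaluation
  b3 <- list(x_px = 19, z_px = 32)     # dx 9 > T_x, dz 12 > T_z
  w3 <- edge_weight(a, b3, P, pars)
  expect_equal(w3,
    0.7 * sqrt(81 + 144) +
    1.2 * 3 * (12 / 5)^2 +
    0.9 * 2 * (9 / 4)^2 +
    1.5 / 13,
    tolerance = 1e-9)

  # spacing caps: no edge
  expect_true(is.na(edge_weight(a, list(x_px = 10 + 20, z_px = 20), P, pars)))
  expect_true(is.na(edge_weight(a, list(x_px = 12, z_px = 20 + 25), P, pars)))
  expect_true(is.na(edge_weight(a, list(x_px = 9, z_px = 25), P, pars)))
})

test_that("vectorized edge building agrees with the scalar weight", {
  set.seed(5)
  pars <- csi_params()
  P <- matrix(runif(100 * 80), 100, 80)
  nodes <- tibble::tibble(x_px = sample(0:79, 12), z_px = sample(30:90, 12),
                          p = runif(12))
  ge <- choroidseg:::build_csi_edges(nodes, P, pars)
  expect_gt(nrow(ge$edges), 0)
  for (k in sample(nrow(ge$edges), min(12, nrow(ge$edges)))) {
    a <- ge$nodes[ge$edges$from[k], ]
    b <- ge$nodes[ge$edges$to[k], ]
    expect_equal(ge$edges$w[k], edge_weight(a, b, P, pars), tolerance = 1e-9)
  }
  # spacing rule: no emitted edge violates the caps
  dx <- ge$nodes$x_px[ge$edges$to] - ge$nodes$x_px[ge$edges$from]
  dz <- ge$nodes$z_px[ge$edges$to] - ge$nodes$z_px[ge$edges$from]
  expect_true(all(dx > 0 & dx < 5 * pars$T_x & abs(dz) < 5 * pars$T_z))
})

test_that("segment scores combine W_sum, W_mean and W_height", {
  pars <- csi_params(A_s = 0.4, A_m = 0.3, A_h = 0.3)
  one <- tibble::tibble(x_px = 0, z_px = 100, p = 1)
  s <- score_segment(one, pars)
  expect_equal(s$W_sum, 1)
  expect_equal(s$W_mean, 1)
  expect_equal(s$W_height, 1 / 100)
  expect_equal(s$score, 0.4 + 0.3 + 0.3 / 100, tolerance = 1e-12)

  nodes <- tibble::tibble(x_px = 0:3, z_px = c(50, 60, 70, 80),
                          p = c(0.2, 0.4, 0.1, 0.3))
  s1 <- score_segment(nodes, pars)
  nodes2 <- nodes
  nodes2$p <- nodes$p * 2
  s2 <- score_segment(nodes2, pars)
  expect_equal(s2$W_sum, 2 * s1$W_sum)
  expect_equal(s2$W_mean, 2 * s1$W_mean)
  expect_equal(s2$W_height, s1$W_height)

  pars_sum <- csi_params(A_s = 1, A_m = 0, A_h = 0)
  expect_equal(score_segment(nodes, pars_sum)$score, sum(nodes$p))
  expect_error(score_segment(nodes[0, ], pars), "empty")
})

test_that("overlap resolution is greedy by score over x-intervals", {
  seg <- function(x0, x1, score_p) {
    n <- x1 - x0 + 1
    choroidseg:::new_path_segment(
      tibble::tibble(x_px = x0:x1, z_px = 100, p = score_p),
      csi_params(A_s = 1, A_m = 0, A_h = 0))
  }
  # disjoint segments are all kept
  ro <- resolve_overlaps(list(seg(0, 5, 0.5), seg(10, 15, 0.2)), 20)
  expect_length(ro$kept, 2)

  # full overlap: higher score wins
  ro2 <- resolve_overlaps(list(seg(0, 8, 0.9), seg(0, 8, 0.4)), 20)
  expect_length(ro2$kept, 1)
  expect_equal(ro2$kept[[1]]$nodes$p[1], 0.9)

  # chain A[0,10] B[8,20] C[30,40] with B > A > C keeps {B, C}
  A <- seg(0, 10, 0.5); B <- seg(8, 20, 0.8); C <- seg(30, 40, 0.1)
  ro3 <- resolve_overlaps(list(A, B, C), 45)
  expect_length(ro3$kept, 2)
  spans <- sapply(ro3$kept, function(s) min(s$nodes$x_px))
  expect_setequal(spans, c(8, 30))

  # merged trace never holds two nodes in one column
  expect_equal(anyDuplicated(ro3$nodes$x_px), 0L)
})

test_that("segmentation success needs one kept segment with 4 nodes", {
  seg_n <- function(n) {
    choroidseg:::new_path_segment(
      tibble::tibble(x_px = seq_len(n) - 1, z_px = 100, p = 0.5), csi_params())
  }
  expect_true(bscan_segmented(list(seg_n(4))))
  expect_false(bscan_segmented(list(seg_n(3), seg_n(3), seg_n(3))))
  expect_false(bscan_segmented(list()))
})

test_that("clean phantom yields one spanning segment; split fields give two", {
  sc <- ph_scales()
  ph <- small_phantom("clean", 2L)
  tru <- ph$truth$traces[[1]]
  segs <- trace_csi(ph$volume$bscans[[1]], tru$BM, csi_params(),
                    sc["dx"], sc["dz"])
  expect_length(segs, 1)
  xs <- segs[[1]]$nodes$x_px
  expect_lt(min(xs), 30)
  expect_gt(max(xs), 480)

  # two smooth step fields separated by a gap wider than 5*T_x -> two fragments
  z <- 0:199
  img <- matrix(60, 200, 300)
  img[, 1:80] <- 60 + 130 * plogis((z - 120) / 3)
  img[, 221:300] <- 60 + 130 * plogis((z - 140) / 3)
  bm <- layer_trace(rep(40, 300), layer = "BM")
  segs2 <- trace_csi(img, bm, csi_params(), sc["dx"], sc["dz"])
  expect_length(segs2, 2)

  # a constant image has no nodes at all
  expect_length(trace_csi(matrix(9, 100, 50),
                          layer_trace(rep(10, 50), layer = "BM"),
                          csi_params(), sc["dx"], sc["dz"]), 0)
})
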