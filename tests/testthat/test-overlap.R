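# Isopleth overlap and the cross-type pair correlation function.

shared_grid_iso <- function(center, n = 1500, sd = 800, seed = 1,
                            levels = c(0.5, 0.95)) {
  set.seed(seed)
  X <- sweep(matrix(rnorm(2 * n, sd = sd), ncol = 2), 2, center, "+")
  ud <- kde_ud(X, H = diag(250^2, 2), cellsize = 100,
               xlim = c(-15000, 15000), ylim = c(-15000, 15000))
  ud_isopleths(ud, levels = levels)
}

test_that("identical isopleths overlap 100%, disjoint ones 0%", {
  iso_a <- shared_grid_iso(c(0, 0), seed = 71)
  iso_b <- shared_grid_iso(c(0, 0), seed = 71)
  ov <- kde_overlap(iso_a, iso_b)
  expect_equal(ov$overlap_pct, c(100, 100))
  expect_equal(ov$overlap, ov$penguin_area)
  iso_c <- shared_grid_iso(c(9000, 9000), seed = 72)
  ov2 <- kde_overlap(iso_a, iso_c)
  expect_equal(ov2$overlap, c(0, 0))
  expect_equal(ov2$overlap_pct, c(0, 0))
})

test_that("relative overlap recomputes from its own absolute outputs", {
  iso_a <- shared_grid_iso(c(0, 0), seed = 73)
  iso_b <- shared_grid_iso(c(1200, -500), seed = 74)
  ov <- kde_overlap(iso_a, iso_b)
  expect_equal(ov$overlap_pct, 100 * ov$overlap / ov$penguin_area,
               tolerance = 1e-12)
  expect_true(all(ov$overlap <= pmin(ov$penguin_area, ov$fishery_area) + 1e-9))
  # partially shifted clouds overlap strictly between 0 and 100
  expect_true(all(ov$overlap_pct > 0 & ov$overlap_pct < 100))
  # grid mismatch is an error
  set.seed(75)
  ud_off <- kde_ud(matrix(rnorm(600, sd = 700), ncol = 2),
                   H = diag(250^2, 2), cellsize = 100)
  expect_error(kde_overlap(iso_a, ud_isopleths(ud_off, c(0.5, 0.95))),
               "different grids")
})

test_that("sub-region restriction reports the region's own area and overlap", {
  iso_a <- shared_grid_iso(c(0, 0), seed = 76)
  iso_b <- shared_grid_iso(c(1500, 0), seed = 77)
  ring <- rbind(c(0, -15000), c(15000, -15000), c(15000, 15000),
                c(0, 15000), c(0, -15000))
  full <- kde_overlap(iso_a, iso_b)
  sub <- kde_overlap(iso_a, iso_b, sub_ring = ring, sub_label = "east_half")
  expect_true(all(sub$penguin_area < full$penguin_area))
  expect_true(all(sub$overlap <= full$overlap + 1e-9))
  expect_equal(unique(sub$region), "east_half")
})

test_that("cross-PCF matches a naive double-loop oracle under both corrections", {
  set.seed(81)
  xlim <- c(0, 4000); ylim <- c(0, 3000)
  Pi <- cbind(runif(20, xlim[1], xlim[2]), runif(20, ylim[1], ylim[2]))
  Pj <- cbind(runif(20, xlim[1], xlim[2]), runif(20, ylim[1], ylim[2]))
  w <- pcf_window(xlim = xlim, ylim = ylim)
  r <- seq(100, 2000, by = 100)
  bw <- 250; n_angles <- 360
  got <- cross_pcf(Pi, Pj, w, r = r, bw = bw, n_angles = n_angles)
  oracle <- naive_pcf_rect(Pi, Pj, xlim, ylim, r, bw, n_angles)
  expect_equal(got$g_iso, oracle$g_iso, tolerance = 1e-10)
  expect_equal(got$g_trans, oracle$g_trans, tolerance = 1e-10)
})

test_that("cross-PCF input contracts are enforced", {
  w <- pcf_window(xlim = c(0, 1000), ylim = c(0, 1000))
  P <- cbind(runif(10, 0, 1000), runif(10, 0, 1000))
  expect_error(cross_pcf(P[1, , drop = FALSE], P, w), "at least 2")
  expect_error(cross_pcf(P, P, w, r = c(0, 100)), "strictly positive")
  expect_error(cross_pcf(P, P + 5000, w), "inside the window")
})

test_that("independent Poisson patterns give g near 1 (CSR)", {
  set.seed(82)
  xlim <- c(0, 5000); ylim <- c(0, 5000)
  w <- pcf_window(xlim = xlim, ylim = ylim)
  r <- seq(300, 2000, by = 100)
  reps <- 60
  acc <- matrix(0, reps, length(r))
  for (k in seq_len(reps)) {
    Pi <- cbind(runif(60, xlim[1], xlim[2]), runif(60, ylim[1], ylim[2]))
    Pj <- cbind(runif(60, xlim[1], xlim[2]), runif(60, ylim[1], ylim[2]))
    acc[k, ] <- cross_pcf(Pi, Pj, w, r = r, corrections = "translation",
                          n_angles = 128)$g_trans
  }
  expect_lt(max(abs(colMeans(acc) - 1)), 0.1)
})

test_that("a 100 m co-clustered pattern peaks near r = 100 m and decays", {
  set.seed(83)
  xlim <- c(0, 6000); ylim <- c(0, 6000)
  w <- pcf_window(xlim = xlim, ylim = ylim)
  Pi <- cbind(runif(150, 500, 5500), runif(150, 500, 5500))
  jit <- matrix(rnorm(2 * nrow(Pi), 0, 100 / sqrt(2)), ncol = 2)
  Pj <- Pi + jit  # |v - u| ~ Rayleigh(100/sqrt 2): mode at 100 m
  keep <- Pj[, 1] >= xlim[1] & Pj[, 1] <= xlim[2] &
    Pj[, 2] >= ylim[1] & Pj[, 2] <= ylim[2]
  Pj <- Pj[keep, , drop = FALSE]
  r <- seq(25, 2000, by = 25)
  bw <- 75
  cur <- cross_pcf(Pi, Pj, w, r = r, bw = bw, n_angles = 256)
  s <- pcf_summary(cur, "isotropic", threshold = 1.5)
  expect_true(s$has_peak)
  expect_gt(s$peak_g, 5)
  expect_lt(abs(s$peak_r - 100), bw + 25)
  # clustering decays towards independence at large r
  expect_lt(mean(cur$g_iso[r > 1500]), 2)
})

test_that("the translation-corrected estimate is symmetric in i and j", {
  set.seed(84)
  xlim <- c(0, 4000); ylim <- c(0, 4000)
  w <- pcf_window(xlim = xlim, ylim = ylim)
  Pi <- cbind(runif(30, xlim[1], xlim[2]), runif(30, ylim[1], ylim[2]))
  Pj <- cbind(runif(25, xlim[1], xlim[2]), runif(25, ylim[1], ylim[2]))
  r <- seq(200, 1500, by = 100)
  g_ij <- cross_pcf(Pi, Pj, w, r = r, bw = 300, corrections = "translation")
  g_ji <- cross_pcf(Pj, Pi, w, r = r, bw = 300, corrections = "translation")
  expect_equal(g_ij$g_trans, g_ji$g_trans, tolerance = 1e-10)
})

test_that("pcf_summary handles flat and monotone curves", {
  flat <- structure(tibble::tibble(r = seq(100, 1000, 100), g_iso = rep(1, 10)),
                    class = c("cross_pcf", "tbl_df", "tbl", "data.frame"))
  s <- pcf_summary(flat, "isotropic", threshold = 1.5)
  expect_false(s$has_peak)
  expect_true(is.na(s$r_above_min))
  dec <- structure(tibble::tibble(r = seq(100, 1000, 100),
                                  g_iso = seq(5, 0.5, length.out = 10)),
                   class = c("cross_pcf", "tbl_df", "tbl", "data.frame"))
  s2 <- pcf_summary(dec, "isotropic")
  expect_equal(s2$peak_r, 100)
})

test_that("polygonal windows rasterise to the right area and weights stay sane", {
  th <- seq(0, 2 * pi, length.out = 257)
  ring <- cbind(3000 * cos(th), 3000 * sin(th))
  w <- pcf_window(rings = ring, cellsize = 50)
  expect_equal(w$area, pi * 3000^2, tolerance = 0.01)
  # a hole via exclude
  hole <- cbind(1000 * cos(th), 1000 * sin(th))
  w2 <- pcf_window(rings = ring, exclude = list(hole), cellsize = 50)
  expect_equal(w2$area, pi * (3000^2 - 1000^2), tolerance = 0.01)
  set.seed(85)
  rr <- sqrt(runif(40, 0, 1)) * 2800
  aa <- runif(40, 0, 2 * pi)
  Pi <- cbind(rr * cos(aa), rr * sin(aa))
  Pi <- Pi[forageoverlap:::.win_inside(Pi, w), , drop = FALSE]
  Pj <- Pi + 10
  both <- forageoverlap:::.win_inside(Pj, w)
  cur <- cross_pcf(Pi[both, ], Pj[both, ], w, r = seq(100, 1000, 100),
                   bw = 200, n_angles = 128)
  expect_true(all(is.finite(cur$g_iso)) && all(cur$g_iso >= 0))
  expect_true(all(is.finite(cur$g_trans)) && all(cur$g_trans >= 0))
})
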