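# Plug-in bandwidth, gridded KDE, isopleths, erasure.

test_that("plug-in bandwidth is scale-equivariant and tracks the normal-scale rule", {
  set.seed(51)
  X <- matrix(rnorm(2000), ncol = 2)
  H <- bw_plugin(X)
  expect_equal(H, t(H))
  expect_true(all(eigen(H)$values > 0))
  # scale equivariance: H(cX) = c^2 H(X)
  H9 <- bw_plugin(3 * X)
  expect_equal(H9, 9 * H, tolerance = 1e-6)
  # on a standard normal sample the diagonal sits near n^(-1/3)
  ns <- nrow(X)^(-1 / 3)
  expect_lt(abs(H[1, 1] - ns) / ns, 0.30)
  expect_lt(abs(H[2, 2] - ns) / ns, 0.30)
  expect_lt(abs(H[1, 2]), 0.3 * ns)
})

test_that("duplicating every point shrinks the selected bandwidth", {
  set.seed(52)
  X <- matrix(rnorm(600), ncol = 2)
  H1 <- bw_plugin(X)
  H2 <- bw_plugin(rbind(X, X))
  expect_lt(H2[1, 1], H1[1, 1])
  expect_lt(H2[2, 2], H1[2, 2])
})

test_that("degenerate inputs are rejected with guidance", {
  expect_error(bw_plugin(matrix(rnorm(10), ncol = 2)), "8 points")
  line <- cbind(1:20, 2 * (1:20))
  expect_error(bw_plugin(line), "collinear")
})

test_that("gridded KDE equals the naive sum-of-Gaussians oracle", {
  set.seed(53)
  pts <- matrix(runif(6, -1, 1), ncol = 2)
  H <- matrix(c(0.5, 0.1, 0.1, 0.3), 2, 2)
  ud <- kde_ud(pts, H = H, cellsize = 0.9, xlim = c(-4.6, 4.4),
               ylim = c(-4.5, 4.5), trunc_sd = Inf)
  oracle <- naive_kde(pts, H, ud$x, ud$y)
  # same normalisation as the estimator
  oracle <- oracle / (sum(oracle) * 0.9^2)
  expect_equal(ud$z, oracle, tolerance = 1e-12)
})

test_that("KDE mass, centre value, and grid preconditions hold", {
  # grid chosen so a cell centre falls exactly on the point
  ud1 <- kde_ud(matrix(0, 1, 2), H = diag(1, 2), cellsize = 0.1,
                xlim = c(-5.05, 5.05), ylim = c(-5.05, 5.05), trunc_sd = Inf)
  expect_equal(max(ud1$z), 1 / (2 * pi), tolerance = 1e-4)
  expect_equal(sum(ud1$z) * 0.1^2, 1, tolerance = 1e-6)
  set.seed(54)
  X <- matrix(rnorm(500), ncol = 2)
  ud <- kde_ud(X, H = diag(0.05, 2), cellsize = 0.05)
  expect_equal(sum(ud$z) * 0.05^2, 1, tolerance = 1e-6)
  expect_true(all(ud$z >= 0))
  expect_error(kde_ud(X, H = diag(0.05, 2), cellsize = 0.05,
                      xlim = c(-1, 1), ylim = c(-1, 1)), "grid too small")
})

test_that("isopleths nest, hold the right mass, and match the analytic normal HDR", {
  set.seed(55)
  X <- matrix(rnorm(8000), ncol = 2)
  ud <- kde_ud(X, H = diag(0.02, 2), cellsize = 0.05)
  iso <- ud_isopleths(ud, levels = c(0.5, 0.75, 0.95))
  # nesting of areas and thresholds
  expect_true(all(diff(iso$area) > 0))
  expect_true(all(diff(iso$threshold) < 0))
  # mass inside the 50% region: at least 0.5, within one cell of it
  cellmass <- max(ud$z) * 0.05^2
  expect_gte(iso$mass[1], 0.5)
  expect_lte(iso$mass[1], 0.5 + cellmass)
  # analytic: 50% HDR of N(0, I) has area 2*pi*ln 2
  expect_equal(iso$area[1], 2 * pi * log(2), tolerance = 0.10)
  expect_error(ud_isopleths(ud, levels = 1.2), "levels")
})

test_that("isopleth masks nest cell-by-cell", {
  set.seed(56)
  X <- matrix(rnorm(1000, sd = 800), ncol = 2)
  ud <- kde_ud(X, H = diag(200^2, 2), cellsize = 100)
  iso <- ud_isopleths(ud, levels = c(0.5, 0.75, 0.95))
  m <- attr(iso, "masks")
  expect_false(any(m[[1]] & !m[[2]]))
  expect_false(any(m[[2]] & !m[[3]]))
})

test_that("KDE is translation-equivariant on the grid", {
  set.seed(57)
  X <- matrix(rnorm(800, sd = 500), ncol = 2)
  H <- diag(150^2, 2)
  shift <- c(1000, -2000)  # multiple of the cell size
  ud1 <- kde_ud(X, H = H, cellsize = 100, xlim = c(-3000, 3000),
                ylim = c(-3000, 3000))
  ud2 <- kde_ud(sweep(X, 2, -shift), H = H, cellsize = 100,
                xlim = c(-3000, 3000) + shift[1],
                ylim = c(-3000, 3000) + shift[2])
  expect_equal(ud1$z, ud2$z, tolerance = 1e-9)
  a1 <- ud_isopleths(ud1, 0.5)$area
  a2 <- ud_isopleths(ud2, 0.5)$area
  expect_equal(a1, a2, tolerance = 1e-9)
})

test_that("halving the cell size moves isopleth areas by under 2%", {
  set.seed(58)
  X <- matrix(rnorm(1200, sd = 2000), ncol = 2)
  H <- diag(500^2, 2)
  a1 <- ud_isopleths(kde_ud(X, H = H, cellsize = 250), c(0.5, 0.95))$area
  a2 <- ud_isopleths(kde_ud(X, H = H, cellsize = 125), c(0.5, 0.95))$area
  expect_lt(max(abs(a1 - a2) / a2), 0.02)
})

test_that("erasure removes land cells and never increases area", {
  co <- coast_geometry()
  # a cloud sitting right on the coastline: roughly half its core on land
  set.seed(59)
  X <- sweep(matrix(rnorm(4000, sd = 1500), ncol = 2), 2,
             c(co$coast_x, -10000), "+")
  ud <- kde_ud(X, H = diag(400^2, 2), cellsize = 100, proj = co$proj)
  iso <- ud_isopleths(ud, levels = c(0.5, 0.95), coast = co,
                      zones = c("island", "mainland"))
  expect_true(all(iso$area_post <= iso$area))
  # symmetric cloud centred on a straight coast: post-erase area is about
  # half (up to sampling noise in the cloud's centring)
  expect_equal(iso$area_post[1] / iso$area[1], 0.5, tolerance = 0.08)
  # independent oracle: the mainland is analytically {x >= coast_x}, so
  # the post-erase area equals the pre-erase mass west of the coastline
  # (the island is nowhere near this cloud)
  grid <- attr(iso, "grid")
  thr_mask <- ud$z >= iso$threshold[1]
  west <- matrix(rep(grid$x < co$coast_x, times = length(grid$y)),
                 length(grid$x))
  oracle_area <- sum(grid$cell_area[thr_mask & west]) / 1e6
  expect_equal(iso$area_post[1], oracle_area, tolerance = 1e-9)
  # a cloud fully at sea is untouched; fully on land erases to zero
  Xsea <- sweep(matrix(rnorm(2000, sd = 800), ncol = 2), 2,
                c(-20000, -20000), "+")
  iso_sea <- ud_isopleths(kde_ud(Xsea, H = diag(300^2, 2), cellsize = 100,
                                 proj = co$proj),
                          levels = 0.5, coast = co)
  expect_equal(iso_sea$area_post, iso_sea$area)
  Xland <- sweep(matrix(rnorm(2000, sd = 800), ncol = 2), 2,
                 c(co$coast_x + 20000, 0), "+")
  iso_land <- ud_isopleths(kde_ud(Xland, H = diag(300^2, 2), cellsize = 100,
                                  proj = co$proj),
                           levels = 0.5, coast = co)
  expect_equal(iso_land$area_post, 0)
})

test_that("erase_excluded composes with already-erased sets", {
  co <- coast_geometry()
  set.seed(60)
  X <- sweep(matrix(rnorm(2000, sd = 2000), ncol = 2), 2,
             c(co$coast_x - 3000, 0), "+")
  ud <- kde_ud(X, H = diag(500^2, 2), cellsize = 250, proj = co$proj)
  iso <- ud_isopleths(ud, levels = 0.5, coast = co,
                      zones = c("island", "mainland"))
  iso2 <- erase_excluded(iso, co, zones = "exclusion_1nm")
  expect_lte(iso2$area_post, iso$area_post)
  iso_direct <- ud_isopleths(ud, levels = 0.5, coast = co,
                             zones = c("island", "mainland", "exclusion_1nm"))
  expect_equal(iso2$area_post, iso_direct$area_post, tolerance = 1e-9)
})

test_that("per-trip home range gives a positive area for a coherent cloud", {
  set.seed(61)
  xy <- matrix(rnorm(120, sd = 1500), ncol = 2)
  hr <- trip_home_range(xy)
  expect_gt(hr, 1)   # a ~1.5 km-sd cloud spans well over 1 km^2
  expect_lt(hr, 500)
  expect_true(is.na(trip_home_range(matrix(c(0, 0, 1, 1), 2, 2))))
})
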