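# Near-shore exclusion, trip segmentation, trip metrics, hourly centroids.

test_that("near-shore exclusion keeps/removes fixes by distance to the island", {
  co <- coast_geometry()
  # points due east of the island shore at 50 m and 150 m
  edge_x <- max(co$island_xy[abs(co$island_xy[, 2]) < 20, 1])
  pts_xy <- rbind(c(edge_x + 50, 0), c(edge_x + 150, 0))
  ll <- proj_inv(pts_xy, co$proj)
  fixes <- tibble::tibble(lon = ll[, 1], lat = ll[, 2])
  kept <- filter_nearshore(fixes, co, radius = 100)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$lon, fixes$lon[2])
})

test_that("near-shore exclusion matches a brute-force buffer oracle", {
  co <- coast_geometry()
  set.seed(41)
  xy <- cbind(runif(400, -4000, 9000), runif(400, -4000, 4000))
  # independent oracle: distance to a densified island boundary
  th <- seq(0, 2 * pi, length.out = 20001)
  bnd <- cbind(co$island_b * cos(th), co$island_a * sin(th))
  d_or <- apply(xy, 1, function(p) {
    if (forageoverlap:::point_in_rings(rbind(p), co$island_xy)) return(0)
    sqrt(min((bnd[, 1] - p[1])^2 + (bnd[, 2] - p[2])^2))
  })
  # avoid points so close to the 100 m threshold that polygon
  # discretisation could flip them
  keep <- abs(d_or - 100) > 20
  xy <- xy[keep, ]; d_or <- d_or[keep]
  ll <- proj_inv(xy, co$proj)
  fixes <- tibble::tibble(lon = ll[, 1], lat = ll[, 2])
  kept <- filter_nearshore(fixes, co, radius = 100)
  expect_equal(nrow(kept), sum(d_or > 100))
  expect_equal(kept$lon, fixes$lon[d_or > 100])
})

dive_row <- function(t0, offs_h, lon, lat, bird = "b01") {
  t <- t0 + offs_h * 3600
  tibble::tibble(bird = bird, start = t, end = t + 60, duration_s = 60,
                 max_depth_m = 10, mean_depth_m = 6, lon = lon, lat = lat)
}

test_that("trips split on long gaps and short trips are flagged", {
  t0 <- as.POSIXct("2022-06-15 12:00:00", tz = "UTC")
  # one continuous bout
  d1 <- dive_row(t0, c(0, 1, 2, 3), lon = c(-71.6, -71.61, -71.62, -71.6),
                 lat = rep(-29.25, 4))
  tr1 <- segment_trips(d1)
  expect_equal(nrow(tr1), 1)
  expect_false(tr1$excluded)
  # two bouts separated by 6 h
  d2 <- dive_row(t0, c(0, 1, 7, 8), lon = c(-71.6, -71.61, -71.62, -71.63),
                 lat = rep(-29.25, 4))
  tr2 <- segment_trips(d2)
  expect_equal(nrow(tr2), 2)
  # a 1.5 h excursion is kept but flagged excluded
  d3 <- dive_row(t0, c(0, 1.5), lon = c(-71.6, -71.61), lat = rep(-29.25, 2))
  tr3 <- segment_trips(d3)
  expect_true(tr3$excluded)
  expect_equal(tr3$reason, "short_trip")
  # a trip with a single distinct fix is flagged
  d4 <- dive_row(t0, c(0, 3), lon = rep(-71.6, 2), lat = rep(-29.25, 2))
  expect_equal(segment_trips(d4)$reason, "too_few_fixes")
})

test_that("trip metrics recover geometry: out-and-back due north", {
  t0 <- as.POSIXct("2022-06-15 12:00:00", tz = "UTC")
  nest <- c(-71.5333, -29.25)
  north <- geosphere::destPoint(nest, 0, 10000)  # 10 km due north
  half <- geosphere::destPoint(nest, 0, 5000)
  d <- dive_row(t0, c(0, 2, 4, 6),
                lon = c(half[1], north[1], north[1], half[1]),
                lat = c(half[2], north[2], north[2], half[2]))
  tr <- segment_trips(d)
  nests <- tibble::tibble(bird = "b01", nest_lon = nest[1], nest_lat = nest[2])
  m <- trip_metrics(tr, nests)
  expect_equal(m$duration_h, 6 + 1 / 60, tolerance = 1e-9)
  expect_equal(m$max_dist_km, 10, tolerance = 1e-4)
  expect_equal(m$mean_bearing_deg, 0, tolerance = 1e-6)
  # total distance equals the brute-force leg sum
  pts <- cbind(d$lon, d$lat)
  legs <- sum(vapply(1:3, function(i)
    geodesic_distance(pts[i, ], pts[i + 1, ]), numeric(1)))
  expect_equal(m$total_dist_km, legs, tolerance = 1e-9)
  expect_gte(m$total_dist_km,
             geodesic_distance(pts[1, ], pts[4, ]))
})

test_that("mean bearing is a circular mean", {
  t0 <- as.POSIXct("2022-06-15 12:00:00", tz = "UTC")
  nest <- c(-71.5333, -29.25)
  p1 <- geosphere::destPoint(nest, 350, 5000)
  p2 <- geosphere::destPoint(nest, 10, 5000)
  d <- dive_row(t0, c(0, 3), lon = c(p1[1], p2[1]), lat = c(p1[2], p2[2]))
  m <- trip_metrics(segment_trips(d),
                    tibble::tibble(bird = "b01", nest_lon = nest[1],
                                   nest_lat = nest[2]))
  expect_equal(m$mean_bearing_deg %% 360, 0, tolerance = 1e-3)
})

test_that("hourly centroids are planar means per bird x date x hour", {
  co <- coast_geometry()
  t0 <- as.POSIXct("2022-06-15 12:00:00", tz = "UTC")
  # single fix: centroid equals the fix
  d1 <- dive_row(t0, 0, lon = -71.60, lat = -29.30)
  c1 <- hourly_centroids(d1, co)
  expect_equal(unname(c(c1$lon, c1$lat)), c(-71.60, -29.30), tolerance = 1e-9)
  # two symmetric fixes in one hour: centroid at the planar midpoint
  xy <- rbind(c(-5000, -3000), c(-3000, -1000))
  ll <- proj_inv(xy, co$proj)
  d2 <- dive_row(t0, c(0, 1 / 60), lon = ll[, 1], lat = ll[, 2])
  c2 <- hourly_centroids(d2, co)
  expect_equal(nrow(c2), 1)
  mid <- proj_inv(rbind(colMeans(xy)), co$proj)
  expect_equal(c(c2$lon, c2$lat), c(mid[1, 1], mid[1, 2]), tolerance = 1e-9)
})

test_that("centroid count equals the brute-force group count on a colony", {
  col <- simulate_colony(small_config(), seed = 17)
  co <- col$coast
  dv <- col$dives_truth
  dv$start <- as.POSIXct(dv$start, origin = "1970-01-01", tz = "UTC")
  dv$bird <- dv$bird
  cent <- hourly_centroids(dv, co, tz_offset_h = -4)
  # oracle group-by on local date-hour strings
  sec <- as.numeric(dv$start) - 4 * 3600
  key <- paste(dv$bird, floor(sec / 86400), floor((sec %% 86400) / 3600))
  expect_equal(nrow(cent), length(unique(key)))
  expect_lte(nrow(cent), nrow(dv))
  expect_true(all(cent$n_fixes >= 1))
})
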