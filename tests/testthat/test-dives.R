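# Dive detection, surface intervals, linking, depth summaries.

series_from <- function(depth, start = "2022-06-15 12:00:00") {
  forageoverlap:::new_sensor_series("b01", as.POSIXct(start, tz = "UTC"), depth)
}

test_that("detection thresholds behave exactly at their boundaries", {
  expect_equal(nrow(detect_dives(series_from(rep(0, 60)))), 0)
  # 10 s surface, 5 s at 1 m, surface: one dive, duration 5 s, max 1 m
  d <- detect_dives(series_from(c(rep(0, 10), rep(1, 5), rep(0, 10))))
  expect_equal(nrow(d), 1)
  expect_equal(d$duration_s, 5)
  expect_equal(d$max_depth_m, 1)
  expect_equal(as.numeric(d$start) - as.numeric(as.POSIXct("2022-06-15 12:00:00", tz = "UTC")), 10)
  # 4 s at 1 m: below minimum duration
  expect_equal(nrow(detect_dives(series_from(c(rep(0, 10), rep(1, 4), rep(0, 10))))), 0)
  # depth below 0.1 never counts
  expect_equal(nrow(detect_dives(series_from(rep(0.09, 60)))), 0)
})

test_that("planted dives are recovered with exact boundaries; sub-threshold excursions are not", {
  set.seed(31)
  n_dives <- 50
  lens <- sample(6:180, n_dives, replace = TRUE)
  starts <- cumsum(sample(20:60, n_dives, replace = TRUE) + c(0, lens[-n_dives]))
  plan <- data.frame(start = starts, len = lens,
                     depth = runif(n_dives, 0.5, 80))
  total <- max(starts + lens) + 100
  depth <- plant_dives(total, plan, noise_sd = 0.02)
  # sub-threshold excursions: too shallow, and too short
  depth[5:15] <- 0.05
  shortpos <- max(starts + lens) + 20
  depth[shortpos:(shortpos + 3)] <- 2
  got <- detect_dives(series_from(depth))
  expect_equal(nrow(got), n_dives)
  t0 <- as.numeric(as.POSIXct("2022-06-15 12:00:00", tz = "UTC"))
  expect_equal(as.numeric(got$start) - t0, plan$start - 1)
  expect_equal(got$duration_s, plan$len)
  expect_equal(got$max_depth_m, plan$depth, tolerance = 1e-12)
})

test_that("detection is monotone in both thresholds and ignores trailing padding", {
  set.seed(32)
  plan <- data.frame(start = c(20, 100, 300), len = c(5, 8, 40),
                     depth = c(0.3, 2, 15))
  depth <- plant_dives(400, plan, noise_sd = 0.02)
  base <- nrow(detect_dives(series_from(depth)))
  expect_gte(base, nrow(detect_dives(series_from(depth), min_depth = 0.5)))
  expect_gte(base, nrow(detect_dives(series_from(depth), min_duration = 10)))
  expect_lte(base, nrow(detect_dives(series_from(depth), min_depth = 0.05)))
  padded <- detect_dives(series_from(c(depth, rep(0, 500))))
  expect_equal(nrow(padded), base)
  expect_equal(padded$start, detect_dives(series_from(depth))$start)
})

test_that("non-uniform series are rejected with guidance", {
  df <- data.frame(time = as.POSIXct("2022-06-15 12:00:00", tz = "UTC") +
                     c(0, 1, 2, 10, 11),
                   depth = c(0, 1, 1, 1, 0), bird = "b01")
  expect_error(detect_dives(df), "non-uniform")
})

test_that("n dives yield n+1 surface intervals with fixes routed correctly", {
  span <- as.POSIXct("2022-06-15 12:00:00", tz = "UTC") + c(0, 300)
  dives <- tibble::tibble(
    bird = "b01",
    start = span[1] + c(90, 110), end = span[1] + c(100, 140),
    duration_s = c(10, 30), max_depth_m = c(5, 8), mean_depth_m = c(3, 6))
  # zero dives: one interval spanning the series
  si0 <- build_surface_intervals(dives[0, ], span)
  expect_equal(nrow(si0), 1)
  expect_equal(as.numeric(si0$end - si0$start, units = "secs"), 300)
  # two dives: three intervals with boundaries at dive starts/ends
  fixes <- tibble::tibble(bird = "b01", time = span[1] + c(50, 95, 105, 200),
                          lon = c(1, 2, 3, 4), lat = c(1, 2, 3, 4))
  expect_warning(si <- build_surface_intervals(dives, span, fixes),
                 "inside a dive")
  expect_equal(nrow(si), 3)
  expect_equal(as.numeric(si$start), as.numeric(c(span[1], dives$end)))
  expect_equal(as.numeric(si$end), as.numeric(c(dives$start, span[2])))
  # fix at t=95 fell inside dive 1 and was rejected; others routed
  expect_equal(si$n_fixes, c(1L, 1L, 1L))
  # overlapping dives are an error
  bad <- dives; bad$start[2] <- bad$start[1] + 5
  expect_error(build_surface_intervals(bad, span, fixes), "overlapping")
})

test_that("dives link to the last fix of the preceding interval", {
  span <- as.POSIXct("2022-06-15 12:00:00", tz = "UTC") + c(0, 300)
  dives <- tibble::tibble(
    bird = "b01", start = span[1] + c(110, 200), end = span[1] + c(150, 240),
    duration_s = c(40, 40), max_depth_m = c(5, 5), mean_depth_m = c(3, 3))
  fixes <- tibble::tibble(bird = "b01", time = span[1] + c(95, 105),
                          lon = c(10, 20), lat = c(-1, -2))
  si <- build_surface_intervals(dives, span, fixes)
  linked <- link_dives(dives, si)
  expect_equal(linked$lon[1], 20)  # the later of the two fixes
  expect_true(is.na(linked$lon[2]))  # empty preceding interval
  expect_error(link_dives(dives, si[1:2, ]), "mismatch")
})

test_that("colony-scale linking agrees with a brute-force oracle", {
  col <- simulate_colony(small_config(), seed = 13)
  for (b in names(col$sensors)[1:2]) {
    ser <- col$sensors[[b]]
    dv <- detect_dives(ser)
    fx <- col$fixes[col$fixes$bird == b, ]
    si <- suppressWarnings(build_surface_intervals(
      dv, c(ser$start, ser$start + length(ser$depth)), fx))
    linked <- link_dives(dv, si)
    # oracle: last fix strictly before the dive start and after the
    # previous dive's end
    ft <- as.numeric(fx$time)
    prev_end <- c(as.numeric(ser$start), as.numeric(dv$end)[-nrow(dv)])
    for (i in seq_len(nrow(dv))) {
      ok <- which(ft >= prev_end[i] & ft < as.numeric(dv$start[i]))
      if (length(ok) == 0) {
        expect_true(is.na(linked$lon[i]))
      } else {
        expect_equal(linked$lon[i], fx$lon[max(ok)])
      }
    }
  }
})

test_that("depth histogram conserves counts and shares match arithmetic", {
  dv <- tibble::tibble(max_depth_m = c(4, 6, 31))
  h <- depth_histogram(dv)
  expect_equal(sum(h$count), 3)
  expect_equal(attr(h, "bin_width"), 5)
  expect_equal(depth_share(dv, 30), 200 / 3, tolerance = 1e-9)
  expect_error(depth_share(dv[0, ], 30), "empty")
  # the published-count arithmetic: 8513 of 11733 at <= 30 m is 72.56%
  big <- tibble::tibble(max_depth_m = c(rep(10, 8513), rep(40, 11733 - 8513)))
  expect_equal(depth_share(big, 30), 72.56, tolerance = 0.005)
  hb <- depth_histogram(big)
  expect_equal(sum(hb$count), 11733)
  # half-open bins: a 5 m dive falls in [5,10)
  h5 <- depth_histogram(tibble::tibble(max_depth_m = 5))
  expect_equal(h5$bin_lower[h5$count > 0], 5)
})
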