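# Synthetic colony and fishery generator. Produces ground-truthed
# deployments (true paths, dive schedules) plus their sensor renderings
# (1 Hz depth trace, duty-cycled GPS fixes) and clustered fishing-set
# patterns, so every downstream stage can be validated against known truth.

# ---- elementary draws -------------------------------------------------------

draw_depths <- function(n, cfg) {
  if (n == 0) return(numeric(0))
  shallow <- stats::runif(n) < cfg$depth_p_shallow
  d <- numeric(n)
  ns <- sum(shallow)
  if (ns > 0) {
    # rejection into (depth_min, 30]
    out <- numeric(0)
    while (length(out) < ns) {
      cand <- stats::rgamma(2 * ns, cfg$depth_shallow_shape, scale = cfg$depth_shallow_scale)
      out <- c(out, cand[cand > cfg$depth_min & cand <= 30])
    }
    d[shallow] <- out[seq_len(ns)]
  }
  nd <- n - ns
  if (nd > 0) {
    out <- numeric(0)
    while (length(out) < nd) {
      cand <- 30 + stats::rgamma(2 * nd, cfg$depth_deep_shape, scale = cfg$depth_deep_scale)
      out <- c(out, cand[cand <= cfg$depth_deep_max])
    }
    d[!shallow] <- out[seq_len(nd)]
  }
  d
}

draw_durations <- function(n, cfg) {
  pmin(pmax(round(stats::rlnorm(n, cfg$dur_meanlog, cfg$dur_sdlog)), cfg$dur_min), cfg$dur_max)
}

draw_surfaces <- function(n, cfg) {
  pmax(round(stats::rlnorm(n, cfg$surf_meanlog, cfg$surf_sdlog)), cfg$surf_min)
}

# Deterministic within-dive depth profile: descend / bottom / ascend,
# bottom at exactly `maxd`; every sample >= 0.2 m so detection at the
# 0.1 m threshold recovers the exact run.
dive_profile <- function(n_s, maxd) {
  desc <- max(1L, floor(0.3 * n_s))
  asc <- max(1L, floor(0.3 * n_s))
  bottom <- n_s - desc - asc
  if (bottom < 1L) { desc <- max(1L, desc - 1L); bottom <- n_s - desc - asc }
  c(seq(0.2, maxd, length.out = desc + 1)[-1],
    rep(maxd, bottom),
    seq(maxd, 0.2, length.out = asc + 1)[-(asc + 1)])
}

# ---- dive schedule ----------------------------------------------------------

# Alternating dive/surface cycles inside the local daylight window, with
# occasional surface loafing so the realised rate tracks dive_rate_per_h.
dive_schedule <- function(t0n, t1n, cfg) {
  if (cfg$dive_rate_per_h == 0 || t1n - t0n < 120) {
    return(tibble::tibble(start = numeric(0), end = numeric(0), max_depth = numeric(0)))
  }
  e_d <- min(exp(cfg$dur_meanlog + cfg$dur_sdlog^2 / 2), cfg$dur_max)
  e_s <- exp(cfg$surf_meanlog + cfg$surf_sdlog^2 / 2)
  occupancy <- min(1, cfg$dive_rate_per_h * (e_d + e_s) / 3600)
  p_loaf <- 1 - occupancy

  starts <- ends <- numeric(0)
  t <- t0n + 30
  dw <- cfg$day_window
  repeat {
    if (t >= t1n - 90) break
    lh <- local_hour(t, cfg$tz_offset_h)
    if (lh < dw[1] || lh >= dw[2]) {
      # drift at the surface until the day window opens again
      sec_local <- (as.numeric(t) + cfg$tz_offset_h * 3600)
      day0 <- floor(sec_local / 86400) * 86400
      next_open <- day0 + dw[1] * 3600
      if (sec_local >= next_open) next_open <- next_open + 86400
      t <- next_open - cfg$tz_offset_h * 3600
      next
    }
    if (p_loaf > 0 && stats::runif(1) < p_loaf) {
      t <- t + stats::rexp(1, rate = 1 / 900)
      next
    }
    d <- draw_durations(1, cfg)
    if (t + d > t1n - 60) break
    starts <- c(starts, round(t)); ends <- c(ends, round(t) + d)
    t <- t + d + draw_surfaces(1, cfg)
  }
  tibble::tibble(start = starts, end = ends, max_depth = draw_depths(length(starts), cfg))
}

# ---- movement ---------------------------------------------------------------

choose_target <- function(side, cfg, coast) {
  coastal <- side == "east" || stats::runif(1) < cfg$p_coastal_west
  if (coastal) {
    c(coast$coast_x - stats::runif(1, cfg$coastal_offset_km[1], cfg$coastal_offset_km[2]) * 1000,
      stats::runif(1, cfg$coastal_span_km[1], cfg$coastal_span_km[2]) * 1000)
  } else {
    r <- stats::runif(1, cfg$offshore_dist_km[1], cfg$offshore_dist_km[2]) * 1000
    th <- stats::runif(1, cfg$offshore_angle_deg[1], cfg$offshore_angle_deg[2]) * pi / 180
    c(r * cos(th), r * sin(th))
  }
}

# Correlated-random-walk trip path: outbound towards a target, foraging
# around it, then a return-to-nest phase timed so the path closes at the
# nest. Steps that would land on shore (or leave the buffer) are deflected.
trip_path <- function(nest_xy, target, t0n, t1n, cfg, coast) {
  n_steps <- max(2L, floor((t1n - t0n) / cfg$step_s))
  tt <- seq(t0n, by = cfg$step_s, length.out = n_steps + 1)
  tt[n_steps + 1] <- t1n
  xy <- matrix(0, n_steps + 1, 2)
  xy[1, ] <- nest_xy
  phase <- "out"
  h <- atan2(target[2] - nest_xy[2], target[1] - nest_xy[1])
  rmax <- coast$buffer_km * 1000 - 500
  for (k in seq_len(n_steps)) {
    pos <- xy[k, ]
    dt <- tt[k + 1] - tt[k]
    remaining <- t1n - tt[k]
    d_nest <- sqrt(sum((pos - nest_xy)^2))
    if (phase != "return" && remaining * cfg$speed_ms * 0.7 <= d_nest) phase <- "return"
    if (phase == "out" && sqrt(sum((pos - target)^2)) < 1500) phase <- "forage"
    if (phase == "return") {
      goal <- nest_xy
      v <- min(3.5, max(cfg$speed_ms, 1.15 * d_nest / max(remaining, 1)))
      h <- atan2(goal[2] - pos[2], goal[1] - pos[1]) +
        stats::rnorm(1, 0, cfg$heading_sd_deg * pi / 180)
    } else if (phase == "forage") {
      v <- cfg$forage_speed_ms
      if (sqrt(sum((pos - target)^2)) > 3000) {
        h <- atan2(target[2] - pos[2], target[1] - pos[1]) +
          stats::rnorm(1, 0, cfg$heading_sd_deg * pi / 180)
      } else {
        h <- h + stats::rnorm(1, 0, cfg$crw_sd_deg * pi / 180)
      }
    } else {
      v <- cfg$speed_ms
      h <- atan2(target[2] - pos[2], target[1] - pos[1]) +
        stats::rnorm(1, 0, cfg$heading_sd_deg * pi / 180)
    }
    step <- v * dt * c(cos(h), sin(h))
    cand <- pos + step
    if (on_land(rbind(cand), coast) || sqrt(sum(cand^2)) > rmax) {
      placed <- FALSE
      for (dh in c(1, -1) * rep(seq(30, 180, by = 30), each = 2) * pi / 180) {
        cand2 <- pos + v * dt * c(cos(h + dh), sin(h + dh))
        if (!on_land(rbind(cand2), coast) && sqrt(sum(cand2^2)) <= rmax) {
          cand <- cand2; h <- h + dh; placed <- TRUE; break
        }
      }
      if (!placed) cand <- pos
    }
    xy[k + 1, ] <- cand
  }
  xy[n_steps + 1, ] <- nest_xy
  cbind(t = tt, x = xy[, 1], y = xy[, 2])
}

path_interp <- function(path, t) {
  cbind(stats::approx(path[, "t"], path[, "x"], xout = t, rule = 2)$y,
        stats::approx(path[, "t"], path[, "y"], xout = t, rule = 2)$y)
}

# Push points that interpolated onto shore back into open water.
nudge_to_water <- function(xy, coast) {
  bad <- which(on_land(xy, coast))
  for (i in bad) {
    p <- xy[i, ]
    dir <- if (point_in_rings(rbind(p), coast$island_xy)) {
      d <- p / max(sqrt(sum(p^2)), 1); d
    } else {
      c(-1, 0)  # mainland: move west, off the coast
    }
    for (k in 1:80) {
      p2 <- p + dir * 100 * k
      if (!on_land(rbind(p2), coast)) { xy[i, ] <- p2; break }
    }
  }
  xy
}

# ---- trips and birds --------------------------------------------------------

#' Simulate one foraging trip with ground truth
#'
#' Generates a correlated-random-walk trip departing from and returning to
#' the nest, with a dive schedule placed along the path. East-side birds
#' head for the mainland coastal strip; west-side birds forage offshore,
#' diverting to the coastal strip with probability
#' `config$p_coastal_west`.
#'
#' @param nest_xy Nest position, projected metres (length-2 numeric).
#' @param side `"east"` or `"west"`.
#' @param t0 Trip start (POSIXct UTC or numeric seconds).
#' @param duration_h Trip duration (h); drawn from the configured
#'   distribution when `NULL`.
#' @param config A [sim_config()] object.
#' @param coast A [coast_geometry()] object.
#' @return List with `path` (matrix `t`, `x`, `y`), `dives` (tibble with
#'   `start`, `end`, `max_depth`, `mean_depth`, `x`, `y`), `t0`, `t1`
#'   (numeric seconds), and `target`.
#' @export
simulate_trip <- function(nest_xy, side, t0, duration_h = NULL,
                          config = sim_config(), coast = coast_geometry()) {
  stopifnot(side %in% c("east", "west"))
  t0n <- round(as.numeric(t0))
  if (is.null(duration_h)) {
    duration_h <- min(stats::rlnorm(1, config$trip_meanlog, config$trip_sdlog), 48)
  }
  t1n <- t0n + round(duration_h * 3600)
  target <- choose_target(side, config, coast)
  path <- trip_path(nest_xy, target, t0n, t1n, config, coast)
  dv <- dive_schedule(t0n, t1n, config)
  if (nrow(dv) > 0) {
    pos <- nudge_to_water(path_interp(path, dv$start), coast)
    dv$mean_depth <- vapply(seq_len(nrow(dv)),
                            function(i) mean(dive_profile(dv$end[i] - dv$start[i], dv$max_depth[i])),
                            numeric(1))
    dv$x <- pos[, 1]; dv$y <- pos[, 2]
  } else {
    dv$mean_depth <- numeric(0); dv$x <- numeric(0); dv$y <- numeric(0)
  }
  list(path = path, dives = dv, t0 = t0n, t1 = t1n, target = target)
}

simulate_bird <- function(bird_id, nest_xy, side, season, deploy_start, days,
                          config, coast) {
  d0 <- round(as.numeric(deploy_start))
  d1 <- d0 + days * 86400
  trips <- list()
  t <- d0 + round(stats::runif(1, 0.5, 2) * 3600)
  while (t < d1 - 3 * 3600) {
    dur <- min(stats::rlnorm(1, config$trip_meanlog, config$trip_sdlog), 48)
    dur <- min(dur, (d1 - t) / 3600 - 0.5)
    if (dur < 1) break
    tr <- simulate_trip(nest_xy, side, t, dur, config, coast)
    trips[[length(trips) + 1]] <- tr
    t <- tr$t1 + round(stats::rlnorm(1, config$rest_meanlog, config$rest_sdlog) * 3600)
  }
  list(bird = bird_id, season = season, side = side, nest_xy = nest_xy,
       deploy_start = d0, deploy_end = d1, trips = trips)
}

# ---- sensor rendering -------------------------------------------------------

new_sensor_series <- function(bird, start, depth, rate = 1, temperature = NULL) {
  structure(list(bird = bird,
                 start = as.POSIXct(start, origin = "1970-01-01", tz = "UTC"),
                 rate = rate, depth = depth, temperature = temperature),
            class = "sensor_series")
}

#' @export
print.sensor_series <- function(x, ...) {
  cat(sprintf("<sensor_series> bird %s, %d samples @ %g Hz from %s\n",
              x$bird, length(x$depth), x$rate,
              format(x$start, "%Y-%m-%d %H:%M:%S UTC")))
  invisible(x)
}

#' Render logger sensors for one simulated bird
#'
#' Turns a bird's ground truth into what the logger would have recorded: a
#' 1 Hz depth trace (zero-mean surface noise, deterministic dive profiles
#' reproducing each scheduled dive) and duty-cycled GPS fixes. Fixes are
#' only produced while the bird is at the surface; each at-sea surface
#' interval of length s is dropped wholesale with probability
#' exp(-s / `dropout_tau`), emulating failed satellite acquisition during
#' brief surfacings.
#'
#' @param bird_truth Output of the internal per-bird simulation (element of
#'   `simulate_colony()$truth`).
#' @inheritParams simulate_trip
#' @return List with `series` (a `sensor_series`) and `fixes` (tibble:
#'   `bird`, `time`, `lon`, `lat`, `source`).
#' @export
render_sensors <- function(bird_truth, config = sim_config(),
                           coast = coast_geometry()) {
  cfg <- config
  d0 <- bird_truth$deploy_start; d1 <- bird_truth$deploy_end
  n <- d1 - d0
  depth <- pmax(stats::rnorm(n, 0, cfg$surface_noise_sd), -0.5)
  for (tr in bird_truth$trips) {
    if (nrow(tr$dives) == 0) next
    for (i in seq_len(nrow(tr$dives))) {
      i0 <- tr$dives$start[i] - d0 + 1L
      ns <- tr$dives$end[i] - tr$dives$start[i]
      depth[i0:(i0 + ns - 1L)] <- dive_profile(ns, tr$dives$max_depth[i])
    }
  }

  # GPS candidates on the absolute duty-cycle grid
  day_ticks <- seq(ceiling(d0 / cfg$gps_day_interval) * cfg$gps_day_interval,
                   d1, by = cfg$gps_day_interval)
  night_ticks <- seq(ceiling(d0 / cfg$gps_night_interval) * cfg$gps_night_interval,
                     d1, by = cfg$gps_night_interval)
  lh_day <- local_hour(day_ticks, cfg$tz_offset_h)
  is_day <- lh_day >= cfg$day_window[1] & lh_day < cfg$day_window[2]
  day_ticks <- day_ticks[is_day]
  lh_night <- local_hour(night_ticks, cfg$tz_offset_h)
  night_ticks <- night_ticks[!(lh_night >= cfg$day_window[1] & lh_night < cfg$day_window[2])]
  ticks <- c(day_ticks, night_ticks)
  src <- rep(c("day", "night"), c(length(day_ticks), length(night_ticks)))
  o <- order(ticks); ticks <- ticks[o]; src <- src[o]

  keep <- logical(length(ticks))
  pos <- matrix(NA_real_, length(ticks), 2)
  in_trip <- rep(FALSE, length(ticks))
  for (tr in bird_truth$trips) {
    sel <- which(ticks >= tr$t0 & ticks < tr$t1)
    if (length(sel) == 0) next
    in_trip[sel] <- TRUE
    dv <- tr$dives
    if (nrow(dv) > 0) {
      idx <- findInterval(ticks[sel], dv$start)
      diving <- idx >= 1 & ticks[sel] < dv$end[pmax(idx, 1)]
      # surface-interval id: 1..k+1, bounded by dive ends
      si <- findInterval(ticks[sel], c(tr$t0, dv$end))
      si_len <- c(dv$start, tr$t1) - c(tr$t0, dv$end)
      p_drop <- if (cfg$dropout_tau > 0) exp(-pmax(si_len, 0) / cfg$dropout_tau) else rep(0, length(si_len))
      dropped <- stats::runif(length(si_len)) < p_drop
      ok <- !diving & !dropped[si]
    } else {
      ok <- rep(TRUE, length(sel))
    }
    keep[sel] <- ok
    if (any(ok)) pos[sel[ok], ] <- path_interp(tr$path, ticks[sel[ok]])
  }
  at_colony <- !in_trip
  keep[at_colony] <- TRUE
  pos[at_colony, 1] <- bird_truth$nest_xy[1]
  pos[at_colony, 2] <- bird_truth$nest_xy[2]

  ticks <- ticks[keep]; src <- src[keep]; pos <- pos[keep, , drop = FALSE]
  pos <- pos + matrix(stats::rnorm(2 * nrow(pos), 0, cfg$gps_error_sd), ncol = 2)
  ll <- proj_inv(pos, coast$proj)
  fixes <- tibble::tibble(
    bird = bird_truth$bird,
    time = as.POSIXct(ticks, origin = "1970-01-01", tz = "UTC"),
    lon = ll[, 1], lat = ll[, 2], source = src)

  temp <- NULL
  if (isTRUE(cfg$temperature)) temp <- 14 - 0.05 * pmax(depth, 0) + stats::rnorm(n, 0, 0.05)
  list(series = new_sensor_series(bird_truth$bird, d0, depth, temperature = temp),
       fixes = fixes)
}

# ---- fishing sets -----------------------------------------------------------

#' Simulate purse-seine fishing sets for one season
#'
#' Thomas-type cluster process (Poisson parents, Gaussian-scattered
#' offspring) restricted to water inside the analysis buffer and outside
#' the 1-nautical-mile exclusion band. Autumn parents sit along the inshore
#' coastal strip; spring parents sit farther south and offshore. When `n`
#' is given (the default takes it from the config) the pattern is
#' conditioned to exactly that many sets.
#'
#' @param season `"autumn"` or `"spring"`.
#' @inheritParams simulate_trip
#' @param n Number of sets; `NA` lets the cluster process decide.
#' @return Tibble: `set_id`, `date`, `lon`, `lat`, `species`, `season`.
#' @export
simulate_fishing_sets <- function(season, config = sim_config(),
                                  coast = coast_geometry(),
                                  n = config$n_sets[[season]]) {
  stopifnot(season %in% c("autumn", "spring"))
  cfg <- config
  sd_m <- cfg$cluster_sd_km[[season]] * 1000
  rmax <- coast$buffer_km * 1000

  region <- if (season == "autumn") {
    list(x = c(coast$coast_x - 5000, coast$coast_x - 2200), y = c(-15000, 8000))
  } else {
    list(x = c(-15000, coast$coast_x - 2600), y = c(-55000, -28000))
  }
  valid <- function(xy) {
    !on_land(xy, coast) &
      !point_in_rings(xy, coast$exclusion_xy) &
      sqrt(xy[, 1]^2 + xy[, 2]^2) <= rmax
  }
  draw_parents <- function(k) {
    out <- matrix(numeric(0), 0, 2)
    while (nrow(out) < k) {
      cand <- cbind(stats::runif(2 * k, region$x[1], region$x[2]),
                    stats::runif(2 * k, region$y[1], region$y[2]))
      out <- rbind(out, cand[valid(cand), , drop = FALSE])
    }
    out[seq_len(k), , drop = FALSE]
  }
  n_par <- max(1L, stats::rpois(1, cfg$set_parents[[season]]))
  parents <- draw_parents(n_par)

  pts <- matrix(numeric(0), 0, 2)
  if (is.na(n)) {
    for (i in seq_len(n_par)) {
      n_off <- stats::rpois(1, cfg$sets_per_parent)
      if (n_off == 0) next
      off <- matrix(rep(parents[i, ], each = n_off), ncol = 2) +
        matrix(stats::rnorm(2 * n_off, 0, sd_m), ncol = 2)
      pts <- rbind(pts, off[valid(off), , drop = FALSE])
    }
  } else {
    while (nrow(pts) < n) {
      i <- ((nrow(pts)) %% n_par) + 1L
      blk <- max(4L, ceiling(n / n_par))
      off <- matrix(rep(parents[i, ], each = blk), ncol = 2) +
        matrix(stats::rnorm(2 * blk, 0, sd_m), ncol = 2)
      pts <- rbind(pts, off[valid(off), , drop = FALSE])
    }
    pts <- pts[seq_len(n), , drop = FALSE]
  }
  m <- nrow(pts)
  if (m == 0) {
    return(tibble::tibble(set_id = character(0), date = as.Date(character(0)),
                          lon = numeric(0), lat = numeric(0),
                          species = character(0), season = character(0)))
  }
  dr <- cfg$season_dates[[season]]
  dates <- sort(dr[1] + sample.int(as.integer(dr[2] - dr[1]) + 1L, m, replace = TRUE) - 1L)
  species <- if (season == "autumn") rep("anchoveta", m) else {
    sample(c("jack_mackerel", "chub_mackerel", "anchoveta"), m,
           replace = TRUE, prob = c(26, 10, 5))
  }
  ll <- proj_inv(pts, coast$proj)
  tibble::tibble(set_id = sprintf("%s_%03d", substr(season, 1, 3), seq_len(m)),
                 date = dates, lon = ll[, 1], lat = ll[, 2],
                 species = species, season = season)
}

# ---- whole colony -----------------------------------------------------------

#' Simulate a full tracked colony plus fishery seasons
#'
#' Generates the coast geometry, nests, per-bird deployments (ground-truth
#' paths and dive schedules), their sensor renderings, and both seasons'
#' fishing sets. With a fixed seed the output is reproducible
#' byte-for-byte.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed (set once at the start); `NULL` leaves the RNG
#'   state alone.
#' @param coast Optional pre-built [coast_geometry()].
#' @return Object of class `penguin_colony`: list with `config`, `coast`,
#'   `birds` (tibble of deployments), `truth` (per-bird ground truth),
#'   `sensors` (named list of `sensor_series`), `fixes` (tibble),
#'   `dives_truth` (tibble of all true dives with season/side), and `sets`
#'   (fishing-set tibble, both seasons).
#' @export
simulate_colony <- function(config = sim_config(), seed = NULL,
                            coast = coast_geometry()) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  birds <- list(); truth <- list(); sensors <- list(); fixes <- list()
  for (season in names(cfg$n_birds)) {
    nb <- cfg$n_birds[[season]]
    ne <- cfg$n_east[[season]]
    nests <- nest_sites(coast, ne, nb - ne)
    dd <- cfg$deploy_dates[[season]]
    for (i in seq_len(nb)) {
      id <- sprintf("%s_%02d", substr(season, 1, 3), i)
      day0 <- dd[1] + sample.int(as.integer(dd[2] - dd[1]) + 1L, 1) - 1L
      # deployments begin 08:00 local
      start <- as.numeric(as.POSIXct(paste(day0, "00:00:00"), tz = "UTC")) +
        (8 - cfg$tz_offset_h) * 3600
      days <- sample(seq(cfg$deployment_days[1], cfg$deployment_days[2]), 1)
      bt <- simulate_bird(id, c(nests$x[i], nests$y[i]), nests$side[i],
                          season, start, days, cfg, coast)
      rs <- render_sensors(bt, cfg, coast)
      truth[[id]] <- bt
      sensors[[id]] <- rs$series
      fixes[[id]] <- rs$fixes
      birds[[id]] <- tibble::tibble(
        bird = id, season = season, side = nests$side[i],
        nest_lon = nests$lon[i], nest_lat = nests$lat[i],
        nest_x = nests$x[i], nest_y = nests$y[i],
        deploy_start = as.POSIXct(start, origin = "1970-01-01", tz = "UTC"),
        deploy_days = days, n_trips = length(bt$trips))
    }
  }
  sets <- dplyr::bind_rows(lapply(names(cfg$n_sets), function(s)
    simulate_fishing_sets(s, cfg, coast)))
  dives_truth <- dplyr::bind_rows(lapply(truth, function(bt) {
    dplyr::bind_rows(lapply(seq_along(bt$trips), function(j) {
      dv <- bt$trips[[j]]$dives
      if (nrow(dv) == 0) return(NULL)
      ll <- proj_inv(cbind(dv$x, dv$y), coast$proj)
      tibble::tibble(bird = bt$bird, season = bt$season, side = bt$side,
                     trip = j, start = dv$start, end = dv$end,
                     max_depth = dv$max_depth, mean_depth = dv$mean_depth,
                     lon = ll[, 1], lat = ll[, 2])
    }))
  }))
  structure(list(config = cfg, coast = coast,
                 birds = dplyr::bind_rows(birds), truth = truth,
                 sensors = sensors, fixes = dplyr::bind_rows(fixes),
                 dives_truth = dives_truth, sets = sets),
            class = "penguin_colony")
}

#' @export
print.penguin_colony <- function(x, ...) {
  cat(sprintf("<penguin_colony> %d birds (%s), %d true dives, %d GPS fixes, %d fishing sets\n",
              nrow(x$birds),
              paste(names(x$config$n_birds), x$config$n_birds, sep = "=", collapse = ", "),
              nrow(x$dives_truth), nrow(x$fixes), nrow(x$sets)))
  invisible(x)
}

#' Simulate trip-level responses for mixed-model validation
#'
#' Draws a balanced trip table from the generative model the seasonal
#' mixed model assumes: log(response) = intercept + beta * spring +
#' bird-level random intercept + residual, with each bird tracked in a
#' single season (as in the study design).
#'
#' @param n_birds Named vector: birds per season.
#' @param trips_per_bird Trips per bird.
#' @param beta_season Season fixed effect (log scale, spring vs autumn).
#' @param sd_bird Between-bird standard deviation (log scale).
#' @param sd_resid Residual standard deviation (log scale).
#' @param mean_log Baseline intercept (log scale).
#' @return Tibble: `bird`, `season`, `value`.
#' @export
simulate_trip_responses <- function(n_birds = c(autumn = 8, spring = 13),
                                    trips_per_bird = 3, beta_season = 0,
                                    sd_bird = 0.3, sd_resid = 0.35,
                                    mean_log = log(16)) {
  rows <- list()
  k <- 0
  for (season in names(n_birds)) {
    for (i in seq_len(n_birds[[season]])) {
      k <- k + 1
      b <- stats::rnorm(1, 0, sd_bird)
      eta <- mean_log + beta_season * (season == "spring") + b +
        stats::rnorm(trips_per_bird, 0, sd_resid)
      rows[[k]] <- tibble::tibble(bird = sprintf("b%02d", k), season = season,
                                  value = exp(eta))
    }
  }
  dplyr::bind_rows(rows)
}
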