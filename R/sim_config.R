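# Configuration for the synthetic colony / fishery generator.

#' Synthetic-study configuration
#'
#' Bundles every tunable of the synthetic-data generator. Defaults encode
#' the study conditions the pipeline is designed for: two breeding seasons
#' with 8 (autumn) and 13 (spring) tracked birds, 1--8 day deployments,
#' duty-cycled GPS (60 s by day, 900 s by night, local day window
#' 07:00--19:00), a dive-depth mixture putting 72.5% of dives at or above
#' 30 m, surface intervals whose length governs fix acquisition
#' (P(no fix) = exp(-interval / `dropout_tau`), yielding roughly 40% of
#' dives with a linked fix), and seasonally contrasting Thomas-cluster
#' fishing-set patterns (54 inshore autumn sets, 43 dispersed southern
#' spring sets).
#'
#' @param n_birds Named integer vector: birds per season.
#' @param n_east Named integer vector: how many of those nest on the
#'   eastern (mainland-facing) shore; the rest nest on the west.
#' @param deployment_days Integer range (days) a logger stays on a bird.
#' @param trip_meanlog,trip_sdlog Lognormal parameters of trip duration (h).
#' @param rest_meanlog,rest_sdlog Lognormal parameters of at-colony rest
#'   duration between trips (h).
#' @param dive_rate_per_h Target dive rate while actively foraging
#'   (dives/h); 0 disables diving entirely.
#' @param depth_p_shallow Fraction of dives drawn from the shallow (<= 30 m)
#'   depth component.
#' @param depth_shallow_shape,depth_shallow_scale Gamma parameters of the
#'   shallow component (m), truncated to (`depth_min`, 30].
#' @param depth_deep_shape,depth_deep_scale Gamma parameters of the deep
#'   component offset (m beyond 30), truncated so depths stay below
#'   `depth_deep_max`.
#' @param depth_min,depth_deep_max Depth bounds (m).
#' @param dur_meanlog,dur_sdlog,dur_min,dur_max Dive duration distribution (s).
#' @param surf_meanlog,surf_sdlog,surf_min Surface-interval distribution (s).
#' @param gps_day_interval,gps_night_interval GPS duty cycle (s); the day
#'   interval must be shorter than the night interval.
#' @param day_window Local clock hours `[from, to)` treated as daylight.
#' @param tz_offset_h Fixed local-time offset from UTC (h).
#' @param dropout_tau Dropout time constant (s): probability that a surface
#'   interval of length s yields no fix is exp(-s / tau); `0` disables
#'   dropout.
#' @param gps_error_sd Isotropic GPS position error (m, 1 sd).
#' @param surface_noise_sd Depth-sensor surface noise (m, 1 sd).
#' @param speed_ms,forage_speed_ms Travel and foraging swim speeds (m/s).
#' @param step_s Path knot spacing (s).
#' @param heading_sd_deg,crw_sd_deg Heading noise while travelling towards a
#'   goal and while foraging (degrees).
#' @param p_coastal_west Probability that a west-nesting bird diverts to the
#'   mainland coastal strip instead of foraging offshore.
#' @param offshore_dist_km Range of offshore target distances (km).
#' @param offshore_angle_deg Range of planar target angles for offshore
#'   trips (math convention: 180 = due west, 270 = due south).
#' @param coastal_offset_km Range of distances west of the mainland coast
#'   for coastal targets (km).
#' @param coastal_span_km Alongshore range `[south, north]` of coastal
#'   targets (km relative to the island latitude).
#' @param n_sets Named vector of fishing-set counts per season (NA = let
#'   the cluster process decide the count).
#' @param set_parents Named vector: mean number of cluster parents.
#' @param sets_per_parent Mean offspring per parent (used when `n_sets` is
#'   NA).
#' @param cluster_sd_km Named vector: Gaussian cluster spread (km).
#' @param season_dates Named list of `c(from, to)` Date ranges for
#'   fishing-set dates.
#' @param deploy_dates Named list of `c(from, to)` Date ranges within which
#'   logger deployments start.
#' @param nearshore_m Near-shore exclusion radius around the island (m).
#' @param gap_threshold_h Trip-splitting gap (h).
#' @param min_trip_h Minimum trip duration; shorter trips are flagged (h).
#' @param cellsize KDE grid cell size (m).
#' @param levels Isopleth probability levels.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(
    n_birds = c(autumn = 8, spring = 13),
    n_east = c(autumn = 3, spring = 5),
    deployment_days = c(1L, 8L),
    trip_meanlog = log(16), trip_sdlog = 0.45,
    rest_meanlog = log(18), rest_sdlog = 0.5,
    dive_rate_per_h = 21,
    depth_p_shallow = 0.725,
    depth_shallow_shape = 2, depth_shallow_scale = 7,
    depth_deep_shape = 2, depth_deep_scale = 12,
    depth_min = 0.3, depth_deep_max = 115,
    dur_meanlog = log(70), dur_sdlog = 0.4, dur_min = 6, dur_max = 300,
    surf_meanlog = log(60), surf_sdlog = 1.0, surf_min = 8,
    gps_day_interval = 60, gps_night_interval = 900,
    day_window = c(7, 19), tz_offset_h = -4,
    dropout_tau = 120, gps_error_sd = 10,
    surface_noise_sd = 0.02,
    speed_ms = 2, forage_speed_ms = 1, step_s = 60,
    heading_sd_deg = 25, crw_sd_deg = 50,
    p_coastal_west = 0.35,
    offshore_dist_km = c(8, 22), offshore_angle_deg = c(160, 260),
    coastal_offset_km = c(0.8, 4), coastal_span_km = c(-12, 10),
    n_sets = c(autumn = 54, spring = 43),
    set_parents = c(autumn = 6, spring = 8),
    sets_per_parent = 9,
    cluster_sd_km = c(autumn = 1.5, spring = 4),
    season_dates = list(autumn = as.Date(c("2022-04-01", "2022-07-31")),
                        spring = as.Date(c("2022-11-01", "2023-02-28"))),
    deploy_dates = list(autumn = as.Date(c("2022-06-15", "2022-06-22")),
                        spring = as.Date(c("2022-11-26", "2022-12-14"))),
    nearshore_m = 100, gap_threshold_h = 4, min_trip_h = 2,
    cellsize = 250, levels = c(0.5, 0.75, 0.95)) {

  cfg <- as.list(environment())

  strictly_pos <- c("trip_sdlog", "rest_sdlog", "dur_sdlog", "surf_sdlog",
                    "gps_day_interval", "gps_night_interval", "dropout_tau",
                    "gps_error_sd", "surface_noise_sd", "speed_ms",
                    "forage_speed_ms", "step_s", "nearshore_m",
                    "gap_threshold_h", "min_trip_h", "cellsize",
                    "depth_shallow_shape", "depth_shallow_scale",
                    "depth_deep_shape", "depth_deep_scale",
                    "dur_min", "surf_min", "depth_min")
  for (nm in strictly_pos) {
    v <- cfg[[nm]]
    if (nm == "dropout_tau") next  # 0 allowed: disables dropout
    if (!all(is.finite(v)) || any(v <= 0)) {
      stop(sprintf("sim_config: `%s` must be strictly positive", nm))
    }
  }
  if (cfg$dropout_tau < 0) stop("sim_config: `dropout_tau` must be >= 0")
  if (cfg$dive_rate_per_h < 0) stop("sim_config: `dive_rate_per_h` must be >= 0")
  probs <- c(cfg$depth_p_shallow, cfg$p_coastal_west)
  if (any(probs < 0 | probs > 1)) stop("sim_config: probabilities must lie in [0, 1]")
  if (!(cfg$gps_day_interval < cfg$gps_night_interval)) {
    stop("sim_config: `gps_day_interval` must be smaller than `gps_night_interval`")
  }
  if (any(cfg$n_birds < 1) || any(cfg$n_east < 0) || any(cfg$n_east > cfg$n_birds)) {
    stop("sim_config: invalid bird counts")
  }
  if (any(cfg$levels <= 0 | cfg$levels >= 1)) stop("sim_config: levels must lie in (0, 1)")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  birds: %s\n", paste(names(x$n_birds), x$n_birds,
                                     sep = "=", collapse = ", ")))
  cat(sprintf("  deployments: %d-%d days; GPS %gs day / %gs night; dropout tau %gs\n",
              x$deployment_days[1], x$deployment_days[2],
              x$gps_day_interval, x$gps_night_interval, x$dropout_tau))
  cat(sprintf("  fishing sets: %s\n", paste(names(x$n_sets), x$n_sets,
                                            sep = "=", collapse = ", ")))
  invisible(x)
}

# Local clock hour (possibly fractional) of POSIXct/numeric UTC times.
local_hour <- function(t, tz_offset_h = -4) {
  ((as.numeric(t) + tz_offset_h * 3600) %% 86400) / 3600
}

# Local calendar date and hour bin of UTC times.
local_date_hour <- function(t, tz_offset_h = -4) {
  sec <- as.numeric(t) + tz_offset_h * 3600
  list(date = as.Date(floor(sec / 86400), origin = "1970-01-01"),
       hour = floor((sec %% 86400) / 3600))
}
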