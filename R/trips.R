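# Foraging-trip segmentation, trip metrics, near-shore exclusion, and
# hourly centroids of dive-linked positions.

#' Remove fixes close to the island shoreline
#'
#' Drops rows whose position lies within `radius` metres of the island
#' polygon (boundary or interior), removing shoreline-geometry and GPS
#' jitter artefacts before spatial analysis.
#'
#' @param fixes Tibble with `lon`, `lat` columns.
#' @param coast A [coast_geometry()] object.
#' @param radius Exclusion radius (m, default 100).
#' @return The filtered tibble.
#' @export
filter_nearshore <- function(fixes, coast, radius = 100) {
  if (nrow(fixes) == 0) return(fixes)
  xy <- proj_fwd(cbind(fixes$lon, fixes$lat), coast$proj)
  d <- dist_to_ring(xy, coast$island_xy, inside_zero = TRUE)
  fixes[d > radius, , drop = FALSE]
}

#' Segment located dives into foraging trips
#'
#' Consecutive located dives of a bird separated by more than
#' `gap_threshold` hours start a new trip (the synthetic colony's
#' inter-trip rests at the colony exceed this gap, so gap-splitting
#' delimits trips exactly there). Trips shorter than `min_trip_h` hours or
#' with fewer than two located fixes are kept but flagged `excluded` with
#' a reason.
#'
#' @param dives Located dive tibble (from [link_dives()]) for one or more
#'   birds; rows without a location are ignored.
#' @param gap_threshold Gap (h) that separates trips.
#' @param min_trip_h Minimum trip duration (h).
#' @return Tibble: one row per (bird, trip) with `bird`, `trip`,
#'   `n_dives`, `start`, `end`, `excluded`, `reason`, and a list-column
#'   `dives` holding the member dives.
#' @export
segment_trips <- function(dives, gap_threshold = 4, min_trip_h = 2) {
  located <- dives[!is.na(dives$lon), , drop = FALSE]
  if (nrow(located) == 0) {
    return(tibble::tibble(bird = character(0), trip = integer(0),
                          n_dives = integer(0),
                          start = as.POSIXct(character(0), tz = "UTC"),
                          end = as.POSIXct(character(0), tz = "UTC"),
                          excluded = logical(0), reason = character(0),
                          dives = list()))
  }
  located <- located[order(located$bird, located$start), , drop = FALSE]
  out <- lapply(split(located, located$bird), function(dd) {
    gaps <- diff(as.numeric(dd$start)) / 3600
    trip_id <- cumsum(c(1, gaps > gap_threshold))
    rows <- lapply(unique(trip_id), function(k) {
      seg <- dd[trip_id == k, , drop = FALSE]
      dur_h <- (as.numeric(seg$end[nrow(seg)]) - as.numeric(seg$start[1])) / 3600
      n_fix <- length(unique(paste(seg$lon, seg$lat)))
      excluded <- FALSE; reason <- NA_character_
      if (dur_h < min_trip_h) { excluded <- TRUE; reason <- "short_trip" }
      if (n_fix < 2) { excluded <- TRUE; reason <- "too_few_fixes" }
      tibble::tibble(bird = seg$bird[1], trip = k, n_dives = nrow(seg),
                     start = seg$start[1], end = seg$end[nrow(seg)],
                     excluded = excluded, reason = reason, dives = list(seg))
    })
    dplyr::bind_rows(rows)
  })
  dplyr::bind_rows(out)
}

#' Compute trip-level spatial metrics
#'
#' Fills in the four trip parameters: duration (start of first to end of
#' last dive, h), maximum geodesic distance from the nest (km), total
#' distance travelled (cumulative geodesic distance between consecutive
#' dive-linked fixes, km), and mean directional bearing of dive-linked
#' fixes from the nest (circular mean, degrees).
#'
#' @param trips Output of [segment_trips()].
#' @param nests Tibble with `bird`, `nest_lon`, `nest_lat`.
#' @return `trips` with columns `duration_h`, `max_dist_km`,
#'   `total_dist_km`, `mean_bearing_deg`, `mean_depth_m`, `max_depth_m`
#'   added (NA for excluded trips with fewer than two fixes).
#' @export
trip_metrics <- function(trips, nests) {
  n <- nrow(trips)
  dur <- maxd <- totd <- brg <- mdep <- xdep <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    seg <- trips$dives[[i]]
    nest <- nests[nests$bird == trips$bird[i], , drop = FALSE]
    if (nrow(nest) == 0) stop(sprintf("no nest for bird %s", trips$bird[i]))
    dur[i] <- (as.numeric(trips$end[i]) - as.numeric(trips$start[i])) / 3600
    mdep[i] <- mean(seg$mean_depth_m %||% seg$max_depth_m)
    xdep[i] <- max(seg$max_depth_m)
    pts <- cbind(seg$lon, seg$lat)
    if (nrow(pts) < 2 && trips$excluded[i]) next
    if (nrow(pts) < 2) stop("trip_metrics: trip with < 2 fixes should have been excluded")
    nest_ll <- c(nest$nest_lon[1], nest$nest_lat[1])
    nm <- matrix(nest_ll, nrow(pts), 2, byrow = TRUE)
    maxd[i] <- max(geodesic_distance(nm, pts))
    totd[i] <- sum(geodesic_distance(pts[-nrow(pts), , drop = FALSE],
                                     pts[-1, , drop = FALSE]))
    distinct <- rowSums(abs(pts - nm)) > 0
    brg[i] <- circular_mean_deg(initial_bearing(nm[distinct, , drop = FALSE],
                                                pts[distinct, , drop = FALSE]))
  }
  dplyr::mutate(trips, duration_h = dur, max_dist_km = maxd,
                total_dist_km = totd, mean_bearing_deg = brg,
                mean_depth_m = mdep, max_depth_m = xdep)
}

#' Aggregate located dives to hourly centroids
#'
#' For each bird, local calendar date, and hour of day, computes the
#' geographic mean of all dive-linked positions: positions are projected
#' to the local plane, averaged, and back-transformed.
#'
#' @param dives Located dive tibble (rows without `lon` are dropped).
#' @param coast A [coast_geometry()] object (provides the projection).
#' @param tz_offset_h Local-time offset from UTC (h) used for hour binning.
#' @return Tibble: `bird`, `date`, `hour`, `lon`, `lat`, `x`, `y`,
#'   `n_fixes`.
#' @export
hourly_centroids <- function(dives, coast, tz_offset_h = -4) {
  located <- dives[!is.na(dives$lon), , drop = FALSE]
  if (nrow(located) == 0) {
    return(tibble::tibble(bird = character(0), date = as.Date(character(0)),
                          hour = integer(0), lon = numeric(0), lat = numeric(0),
                          x = numeric(0), y = numeric(0), n_fixes = integer(0)))
  }
  dh <- local_date_hour(located$start, tz_offset_h)
  xy <- proj_fwd(cbind(located$lon, located$lat), coast$proj)
  df <- tibble::tibble(bird = located$bird, date = dh$date,
                       hour = as.integer(dh$hour), x = xy[, 1], y = xy[, 2])
  agg <- dplyr::summarise(dplyr::group_by(df, .data$bird, .data$date, .data$hour),
                          x = mean(.data$x), y = mean(.data$y),
                          n_fixes = dplyr::n(), .groups = "drop")
  ll <- proj_inv(cbind(agg$x, agg$y), coast$proj)
  dplyr::relocate(dplyr::mutate(agg, lon = ll[, 1], lat = ll[, 2]),
                  "bird", "date", "hour", "lon", "lat", "x", "y", "n_fixes")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
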