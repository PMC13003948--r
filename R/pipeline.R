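# End-to-end analysis: synthetic colony (or externally read data) ->
# dives -> linked locations -> trips -> hourly centroids -> utilisation
# distributions -> overlap and cross-PCF -> seasonal models.

#' Run the full overlap pipeline on a synthetic colony
#'
#' Simulates a colony and both fishery seasons, then runs every analysis
#' stage: dive detection, surface-interval linking, near-shore exclusion,
#' trip segmentation and metrics, hourly centroids, pooled penguin and
#' per-season fishery utilisation distributions on a shared grid
#' (plug-in bandwidths), 50/75/95% isopleths with land (and, for the
#' fishery, 1-nm-zone) erasure, isopleth overlap including a coastal-core
#' sub-region, cross-PCFs against each fishery season, seasonal mixed
#' models, and the depth-use summary.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for the whole run.
#' @param coastal_core_ring Planar ring (m) delimiting the coastal core
#'   sub-region of the penguin utilisation area; `NULL` uses a default
#'   strip along the mainland coast.
#' @param verbose Emit per-stage record counts via [message()].
#' @return Object of class `overlap_analysis` (a list of tibbles and
#'   fitted objects; see the vignette for a tour).
#' @export
run_overlap_pipeline <- function(config = sim_config(), seed = 1,
                                 coastal_core_ring = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  colony <- simulate_colony(config, seed = seed)
  coast <- colony$coast
  say("simulated %d birds, %d true dives, %d fixes, %d fishing sets",
      nrow(colony$birds), nrow(colony$dives_truth), nrow(colony$fixes),
      nrow(colony$sets))

  # dive detection + linking, per bird
  dives <- lapply(names(colony$sensors), function(b) {
    ser <- colony$sensors[[b]]
    dv <- detect_dives(ser)
    span <- c(ser$start, ser$start + length(ser$depth) / ser$rate)
    fx <- colony$fixes[colony$fixes$bird == b, , drop = FALSE]
    si <- suppressWarnings(build_surface_intervals(dv, span, fx))
    link_dives(dv, si)
  })
  dives <- dplyr::bind_rows(dives)
  dives <- dplyr::left_join(dives,
                            colony$birds[, c("bird", "season", "side")],
                            by = "bird")
  linked_fraction <- mean(!is.na(dives$lon))
  say("detected %d dives, %.1f%% with a linked fix", nrow(dives),
      100 * linked_fraction)

  located <- filter_nearshore(dives[!is.na(dives$lon), , drop = FALSE],
                              coast, radius = config$nearshore_m)
  say("%d located dives after %g m near-shore exclusion", nrow(located),
      config$nearshore_m)

  trips <- segment_trips(located, gap_threshold = config$gap_threshold_h,
                         min_trip_h = config$min_trip_h)
  trips <- trip_metrics(trips, colony$birds)
  trips <- dplyr::left_join(trips, colony$birds[, c("bird", "season", "side")],
                            by = "bird")
  say("%d trips (%d excluded)", nrow(trips), sum(trips$excluded))

  cent <- hourly_centroids(located, coast, tz_offset_h = config$tz_offset_h)
  say("%d hourly centroids", nrow(cent))

  # shared analysis grid: buffer plus margin for the kernel tails
  r <- coast$buffer_km * 1000 + 15000
  xlim <- c(-r, r); ylim <- c(-r, r)
  pen_xy <- cbind(cent$x, cent$y)
  ud_pen <- kde_ud(pen_xy, cellsize = config$cellsize, xlim = xlim,
                   ylim = ylim, proj = coast$proj)
  iso_pen <- ud_isopleths(ud_pen, levels = config$levels, coast = coast,
                          zones = c("island", "mainland"))
  say("penguin UD: H trace %.3g km2, 50%% area %.1f km2",
      sum(diag(ud_pen$H)) / 1e6, iso_pen$area_post[iso_pen$level == 0.5])

  seasons <- names(config$n_sets)
  sets_xy <- lapply(seasons, function(s) {
    st <- colony$sets[colony$sets$season == s, , drop = FALSE]
    proj_fwd(cbind(st$lon, st$lat), coast$proj)
  })
  names(sets_xy) <- seasons
  ud_fish <- lapply(seasons, function(s)
    kde_ud(sets_xy[[s]], cellsize = config$cellsize, xlim = xlim,
           ylim = ylim, proj = coast$proj))
  names(ud_fish) <- seasons
  iso_fish <- lapply(seasons, function(s)
    ud_isopleths(ud_fish[[s]], levels = config$levels, coast = coast,
                 zones = c("island", "mainland", "exclusion_1nm")))
  names(iso_fish) <- seasons

  if (is.null(coastal_core_ring)) {
    coastal_core_ring <- rbind(
      c(coast$coast_x - 5500, -20000), c(coast$coast_x + 100, -20000),
      c(coast$coast_x + 100, 15000), c(coast$coast_x - 5500, 15000),
      c(coast$coast_x - 5500, -20000))
  }
  overlap <- dplyr::bind_rows(lapply(seasons, function(s)
    dplyr::mutate(kde_overlap(iso_pen, iso_fish[[s]]), season = s)))
  overlap_core <- dplyr::bind_rows(lapply(seasons, function(s)
    dplyr::mutate(kde_overlap(iso_pen, iso_fish[[s]],
                              sub_ring = coastal_core_ring,
                              sub_label = "coastal_core"), season = s)))
  say("overlap (50%%): %s",
      paste(sprintf("%s %.1f%%", overlap$season[overlap$level == 0.5],
                    overlap$overlap_pct[overlap$level == 0.5]), collapse = ", "))

  # cross-PCF in the buffer-minus-land window
  win <- pcf_window(rings = coast$buffer_xy,
                    exclude = list(coast$island_xy, coast$mainland_xy),
                    cellsize = config$cellsize)
  pcf <- list(); pcf_sum <- list()
  for (s in seasons) {
    Pi <- pen_xy[.win_inside(pen_xy, win), , drop = FALSE]
    Pj <- sets_xy[[s]][.win_inside(sets_xy[[s]], win), , drop = FALSE]
    pcf[[s]] <- cross_pcf(Pi, Pj, win)
    pcf_sum[[s]] <- dplyr::mutate(
      dplyr::bind_rows(pcf_summary(pcf[[s]], "isotropic"),
                       pcf_summary(pcf[[s]], "translation")), season = s)
  }
  pcf_sum <- dplyr::bind_rows(pcf_sum)

  # per-trip home ranges + seasonal models
  ok <- !trips$excluded
  hr <- rep(NA_real_, nrow(trips))
  for (i in which(ok)) {
    seg <- trips$dives[[i]]
    hr[i] <- trip_home_range(proj_fwd(cbind(seg$lon, seg$lat), coast$proj),
                             cellsize = 100, proj = coast$proj)
  }
  trips$home_range_km2 <- hr
  eff <- season_effects(trips[ok, , drop = FALSE])
  say("seasonal models fitted for %d responses", nrow(eff))

  hist30 <- depth_histogram(dives)
  share30 <- depth_share(dives, 30)

  structure(list(
    config = config, seed = seed, coast = coast, colony = colony,
    dives = dives, located = located, trips = trips, centroids = cent,
    ud_penguin = ud_pen, ud_fishery = ud_fish,
    iso_penguin = iso_pen, iso_fishery = iso_fish,
    overlap = overlap, overlap_core = overlap_core,
    pcf = pcf, pcf_summary = pcf_sum,
    season_effects = eff,
    depth_hist = hist30, share_le_30m = share30,
    linked_fraction = linked_fraction,
    coastal_core_ring = coastal_core_ring),
    class = "overlap_analysis")
}

#' @export
print.overlap_analysis <- function(x, ...) {
  cat("<overlap_analysis>\n")
  cat(sprintf("  %d dives (%.1f%% linked), %d centroids, %d trips\n",
              nrow(x$dives), 100 * x$linked_fraction, nrow(x$centroids),
              nrow(x$trips)))
  cat(sprintf("  dives <= 30 m: %.1f%%\n", x$share_le_30m))
  for (s in unique(x$overlap$season)) {
    o <- x$overlap[x$overlap$season == s & x$overlap$level == 0.5, ]
    cat(sprintf("  50%% overlap with %s fishery: %.1f km2 (%.1f%%)\n",
                s, o$overlap, o$overlap_pct))
  }
  invisible(x)
}

#' Write pipeline results to a directory
#'
#' Emits the dive table, trip-metrics table, hourly centroids, isopleth
#' GeoJSONs (penguin + per-season fishery), coast GeoJSON, overlap report
#' (CSV and JSON), per-season cross-PCF curves, the seasonal-model table,
#' and a run summary JSON.
#'
#' @param result An `overlap_analysis` from [run_overlap_pipeline()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_overlap_results <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  dv <- result$dives
  utils::write.csv(
    data.frame(bird = dv$bird, start = .fmt_time(dv$start),
               end = .fmt_time(dv$end), duration_s = dv$duration_s,
               max_depth_m = dv$max_depth_m, mean_depth_m = dv$mean_depth_m,
               lon = ifelse(is.na(dv$lon), "", sprintf("%.7f", dv$lon)),
               lat = ifelse(is.na(dv$lat), "", sprintf("%.7f", dv$lat))),
    p("dives.csv"), row.names = FALSE, quote = FALSE)
  tr <- result$trips
  utils::write.csv(
    data.frame(bird = tr$bird, season = tr$season, trip = tr$trip,
               n_dives = tr$n_dives, duration_h = tr$duration_h,
               max_dist_km = tr$max_dist_km, total_dist_km = tr$total_dist_km,
               mean_bearing_deg = tr$mean_bearing_deg,
               home_range_km2 = tr$home_range_km2,
               excluded = tr$excluded, reason = tr$reason),
    p("trips.csv"), row.names = FALSE, quote = FALSE, na = "")
  utils::write.csv(as.data.frame(result$centroids[, c("bird", "date", "hour",
                                                      "lon", "lat", "n_fixes")]),
                   p("centroids.csv"), row.names = FALSE, quote = FALSE)
  write_isopleths(result$iso_penguin, p("isopleths_penguin.geojson"))
  for (s in names(result$iso_fishery)) {
    write_isopleths(result$iso_fishery[[s]], p(sprintf("isopleths_fishery_%s.geojson", s)))
  }
  write_coast_geojson(result$coast, p("coast.geojson"))
  ov <- rbind(as.data.frame(result$overlap), as.data.frame(result$overlap_core))
  utils::write.csv(ov, p("overlap.csv"), row.names = FALSE, quote = FALSE)
  jsonlite::write_json(ov, p("overlap.json"), dataframe = "rows", digits = NA)
  for (s in names(result$pcf)) {
    utils::write.csv(as.data.frame(result$pcf[[s]]),
                     p(sprintf("crosspcf_%s.csv", s)), row.names = FALSE,
                     quote = FALSE)
  }
  utils::write.csv(as.data.frame(result$season_effects),
                   p("season_effects.csv"), row.names = FALSE, quote = FALSE)
  summary <- list(
    n_dives = nrow(result$dives),
    linked_fraction = result$linked_fraction,
    share_dives_le_30m_pct = result$share_le_30m,
    n_centroids = nrow(result$centroids),
    n_trips = nrow(result$trips),
    penguin_areas_km2 = stats::setNames(as.list(result$iso_penguin$area_post),
                                        sprintf("p%d", round(100 * result$iso_penguin$level))))
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
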