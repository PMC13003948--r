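# Stylised study-area geometry: a breeding island separated from the
# mainland by a channel, the 1-nautical-mile mainland exclusion band, and
# the circular analysis buffer around the island.

#' Build the stylised coast geometry
#'
#' Constructs an island (ellipse, long axis north--south so that the colony
#' has distinct mainland-facing east and ocean-facing west shores), a
#' mainland block to the east whose coastline runs north--south, the
#' 1-nautical-mile fisheries exclusion band hugging the mainland coast, and
#' a circular analysis buffer centred on the island. All polygons are
#' returned in WGS84 lon/lat together with the local projection used to
#' build them.
#'
#' @param center_lon,center_lat Island centroid (decimal degrees). Defaults
#'   place the island off the north-central Chilean coast.
#' @param island_area_km2 Island area (km^2; default 3.01, i.e. 301 ha).
#' @param island_axis_ratio North--south to east--west semi-axis ratio of
#'   the island ellipse.
#' @param channel_km Width of the channel between the island's eastern
#'   shore and the mainland coastline (km; default 6.5).
#' @param exclusion_m Width of the mainland-coast fisheries exclusion band
#'   (m; default 1852, one nautical mile).
#' @param buffer_km Radius of the circular analysis buffer around the
#'   island centroid (km; default 62).
#' @param mainland_span_km Half-length of the mainland block north and
#'   south of the island latitude (km).
#' @param mainland_depth_km Eastward depth of the mainland block (km).
#' @param n_vertices Number of vertices for the island and buffer rings.
#' @return Object of class `coast_geometry`: list with elements `island`,
#'   `mainland`, `exclusion`, `buffer` (closed lon/lat rings), their
#'   projected counterparts (`*_xy`), the `proj` object, and scalar
#'   parameters (`coast_x`, metres east of the island centroid where the
#'   mainland coastline runs).
#' @export
coast_geometry <- function(center_lon = -71.5333, center_lat = -29.25,
                           island_area_km2 = 3.01, island_axis_ratio = 2,
                           channel_km = 6.5, exclusion_m = 1852,
                           buffer_km = 62, mainland_span_km = 90,
                           mainland_depth_km = 40, n_vertices = 256) {
  stopifnot(island_area_km2 > 0, channel_km > 0, exclusion_m > 0,
            buffer_km > channel_km, island_axis_ratio >= 1)
  proj <- local_proj(center_lon, center_lat)

  b <- sqrt(island_area_km2 * 1e6 / (pi * island_axis_ratio))  # E-W semi-axis (m)
  a <- island_axis_ratio * b                                   # N-S semi-axis (m)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)
  island_xy <- cbind(b * cos(th), a * sin(th))

  coast_x <- b + channel_km * 1000
  span <- mainland_span_km * 1000
  depth <- mainland_depth_km * 1000
  mainland_xy <- rbind(
    c(coast_x, -span), c(coast_x + depth, -span),
    c(coast_x + depth, span), c(coast_x, span), c(coast_x, -span))
  exclusion_xy <- rbind(
    c(coast_x - exclusion_m, -span), c(coast_x, -span),
    c(coast_x, span), c(coast_x - exclusion_m, span),
    c(coast_x - exclusion_m, -span))
  buffer_xy <- cbind(buffer_km * 1000 * cos(th), buffer_km * 1000 * sin(th))

  for (ring in list(island_xy, mainland_xy, exclusion_xy, buffer_xy)) {
    if (.ring_self_intersects(ring)) stop("degenerate coast polygon (self-intersection)")
  }

  structure(list(
    proj = proj,
    island = proj_inv(island_xy, proj), island_xy = island_xy,
    mainland = proj_inv(mainland_xy, proj), mainland_xy = mainland_xy,
    exclusion = proj_inv(exclusion_xy, proj), exclusion_xy = exclusion_xy,
    buffer = proj_inv(buffer_xy, proj), buffer_xy = buffer_xy,
    coast_x = coast_x, island_a = a, island_b = b,
    channel_km = channel_km, exclusion_m = exclusion_m,
    buffer_km = buffer_km
  ), class = "coast_geometry")
}

#' @export
print.coast_geometry <- function(x, ...) {
  cat(sprintf(
    "<coast_geometry> island %.2f km2, channel %.1f km, 1-nm band %.0f m, buffer %.0f km\n",
    ring_area_planar(x$island_xy) / 1e6, x$channel_km, x$exclusion_m, x$buffer_km))
  invisible(x)
}

#' Test whether planar points are on land
#'
#' @param xy Two-column matrix of projected coordinates (m).
#' @param coast A [coast_geometry()] object.
#' @param include_island Count the island as land (default TRUE).
#' @return Logical vector.
#' @export
on_land <- function(xy, coast, include_island = TRUE) {
  land <- point_in_rings(xy, coast$mainland_xy)
  if (include_island) land <- land | point_in_rings(xy, coast$island_xy)
  land
}

# Nest sites on the island shoreline. East-side nests sit on the
# mainland-facing arc, west-side nests on the ocean-facing arc.
#' Place nests on the island shoreline
#'
#' @param coast A [coast_geometry()] object.
#' @param n_east,n_west Numbers of east- (mainland-facing) and west-side
#'   nests.
#' @return Tibble with columns `nest_id`, `side`, `lon`, `lat`, `x`, `y`.
#' @export
nest_sites <- function(coast, n_east, n_west) {
  ang_east <- stats::runif(n_east, -70, 70) * pi / 180
  ang_west <- stats::runif(n_west, 110, 250) * pi / 180
  ang <- c(ang_east, ang_west)
  xy <- cbind(0.97 * coast$island_b * cos(ang), 0.97 * coast$island_a * sin(ang))
  ll <- proj_inv(xy, coast$proj)
  tibble::tibble(
    nest_id = seq_len(n_east + n_west),
    side = rep(c("east", "west"), c(n_east, n_west)),
    lon = ll[, 1], lat = ll[, 2], x = xy[, 1], y = xy[, 2])
}
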