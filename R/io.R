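# Readers and writers: logger CSV (1 Hz depth + embedded GPS rows),
# fishing-set CSV with season assignment, and GeoJSON for isopleths and
# coast geometry. Timestamps are stored in UTC (ISO-8601); local time is
# used only for daylight cadence and hour binning.

.fmt_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
.parse_time <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Write a logger deployment to CSV
#'
#' One row per depth sample; GPS fixes are merged onto the sample rows
#' whose timestamp matches the fix (lon/lat empty elsewhere).
#'
#' @param series A `sensor_series`.
#' @param fixes Fix tibble for the same bird (`time`, `lon`, `lat`,
#'   optional `source`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_logger_csv <- function(series, fixes, path) {
  n <- length(series$depth)
  tt <- as.numeric(series$start) + (seq_len(n) - 1L) / series$rate
  lon <- lat <- rep(NA_real_, n)
  src <- rep("", n)
  if (!is.null(fixes) && nrow(fixes) > 0) {
    idx <- match(round(as.numeric(fixes$time)), round(tt))
    ok <- !is.na(idx)
    lon[idx[ok]] <- fixes$lon[ok]; lat[idx[ok]] <- fixes$lat[ok]
    if ("source" %in% names(fixes)) src[idx[ok]] <- fixes$source[ok]
  }
  df <- data.frame(bird = series$bird,
                   time = .fmt_time(as.POSIXct(tt, origin = "1970-01-01", tz = "UTC")),
                   depth = round(series$depth, 4),
                   lon = ifelse(is.na(lon), "", sprintf("%.7f", lon)),
                   lat = ifelse(is.na(lat), "", sprintf("%.7f", lat)),
                   source = src)
  if (!is.null(series$temperature)) df$temperature <- round(series$temperature, 3)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a logger CSV
#'
#' Expects columns `time`, `depth`, `lon`, `lat` (lon/lat may be empty on
#' sensor-only rows) and optionally `bird`, `source`, `temperature`.
#' Validates coordinate bounds and strictly increasing timestamps per
#' bird. Sampling gaps are not interpolated: the trace is split into
#' uniform segments at every gap, one `sensor_series` per segment, with
#' the number of gaps recorded in attribute `n_gaps`.
#'
#' @param path CSV file.
#' @return List with `series` (list of `sensor_series`) and `fixes`
#'   (tibble `bird`, `time`, `lon`, `lat`, `source`).
#' @export
read_logger_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(time = "character"))
  need <- c("time", "depth", "lon", "lat")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop(sprintf("logger CSV format error: missing column(s) %s",
                 paste(miss, collapse = ", ")))
  }
  if (!"bird" %in% names(df)) df$bird <- "unknown"
  tt <- .parse_time(df$time)
  if (anyNA(tt)) stop(sprintf("unparseable timestamp at row %d", which(is.na(tt))[1]))
  df$lon <- suppressWarnings(as.numeric(df$lon))
  df$lat <- suppressWarnings(as.numeric(df$lat))
  has_fix <- !is.na(df$lon) & !is.na(df$lat)
  if (any(has_fix & (df$lon < -180 | df$lon > 180 | df$lat < -90 | df$lat > 90))) {
    stop(sprintf("coordinate out of range at row %d",
                 which(has_fix & (abs(df$lon) > 180 | abs(df$lat) > 90))[1]))
  }
  series <- list(); fixes <- list()
  for (b in unique(df$bird)) {
    sub <- df[df$bird == b, , drop = FALSE]
    st <- as.numeric(tt[df$bird == b])
    if (any(diff(st) <= 0)) {
      stop(sprintf("non-monotone timestamps for bird %s at row %d",
                   b, which(diff(st) <= 0)[1] + 1L))
    }
    dt <- if (length(st) > 1) diff(st) else 1
    rate <- 1 / min(dt)
    brk <- which(abs(dt - min(dt)) > 1e-9)
    seg_start <- c(1L, brk + 1L)
    seg_end <- c(brk, length(st))
    for (k in seq_along(seg_start)) {
      i0 <- seg_start[k]; i1 <- seg_end[k]
      s <- new_sensor_series(b, st[i0], sub$depth[i0:i1], rate = rate,
                             temperature = sub$temperature[i0:i1])
      attr(s, "n_gaps") <- length(brk)
      series[[length(series) + 1]] <- s
    }
    hf <- has_fix[df$bird == b]
    fixes[[b]] <- tibble::tibble(
      bird = b,
      time = as.POSIXct(st[hf], origin = "1970-01-01", tz = "UTC"),
      lon = sub$lon[hf], lat = sub$lat[hf],
      source = if ("source" %in% names(sub)) sub$source[hf] else NA_character_)
  }
  list(series = series, fixes = dplyr::bind_rows(fixes))
}

# Season windows: autumn Apr-Jul, spring Nov-Feb (any year).
.season_from_date <- function(date) {
  m <- as.integer(format(date, "%m"))
  out <- rep(NA_character_, length(m))
  out[m %in% 4:7] <- "autumn"
  out[m %in% c(11, 12, 1, 2)] <- "spring"
  out
}

#' Write fishing sets to CSV
#' @param sets Tibble with `date`, `lon`, `lat`, `species` (and optionally
#'   `set_id`, `season`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fishing_sets <- function(sets, path) {
  df <- as.data.frame(sets)
  df$date <- format(df$date, "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read fishing sets from CSV, assigning seasons from date windows
#'
#' Sets dated April--July are autumn; November--February are spring. Rows
#' outside both windows (the closed months) are dropped with a warning.
#'
#' @param path CSV with columns `date`, `lon`, `lat`, `species`.
#' @return Tibble: `set_id`, `date`, `lon`, `lat`, `species`, `season`.
#' @export
read_fishing_sets <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "lon", "lat", "species")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop(sprintf("fishing-set CSV format error: missing column(s) %s",
                 paste(miss, collapse = ", ")))
  }
  dd <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(dd)) {
    stop(sprintf("unparseable date in row(s): %s",
                 paste(utils::head(which(is.na(dd)), 5), collapse = ", ")))
  }
  if (any(df$lon < -180 | df$lon > 180 | df$lat < -90 | df$lat > 90)) {
    stop("coordinate out of range in fishing-set CSV")
  }
  season <- .season_from_date(dd)
  if (anyNA(season)) {
    warning(sprintf("%d set(s) dated outside the fishing seasons were dropped",
                    sum(is.na(season))))
  }
  keep <- !is.na(season)
  tibble::tibble(
    set_id = if ("set_id" %in% names(df)) df$set_id[keep] else sprintf("set_%03d", which(keep)),
    date = dd[keep], lon = df$lon[keep], lat = df$lat[keep],
    species = df$species[keep], season = season[keep])
}

# ---- GeoJSON ---------------------------------------------------------------

# Group rings into GeoJSON MultiPolygon coordinates: outers first, holes
# attached to the first outer that contains them.
.rings_to_multipolygon <- function(rings) {
  if (length(rings) == 0) return(list())
  hole <- vapply(rings, function(r) isTRUE(attr(r, "hole")), logical(1))
  outers <- which(!hole)
  polys <- lapply(outers, function(i) list(.ring_coords(rings[[i]])))
  for (j in which(hole)) {
    p <- rings[[j]][1, , drop = FALSE]
    parent <- NULL
    for (k in seq_along(outers)) {
      if (point_in_rings(p, rings[[outers[k]]])) { parent <- k; break }
    }
    if (is.null(parent)) parent <- 1L
    polys[[parent]] <- c(polys[[parent]], list(.ring_coords(rings[[j]])))
  }
  polys
}

.ring_coords <- function(ring) {
  m <- .as_coord_matrix(ring)
  if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])
  lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
}

#' Write an isopleth set to GeoJSON
#'
#' One MultiPolygon feature per level with properties `level` and
#' `area_km2` (the post-erase area). An empty set writes an empty
#' FeatureCollection.
#'
#' @param iso An `isopleth_set` from [ud_isopleths()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_isopleths <- function(iso, path) {
  features <- lapply(seq_len(nrow(iso)), function(k) {
    list(type = "Feature",
         properties = list(level = iso$level[k], area_km2 = iso$area_post[k]),
         geometry = list(type = "MultiPolygon",
                         coordinates = .rings_to_multipolygon(iso$polygons[[k]])))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an isopleth GeoJSON written by [write_isopleths()]
#'
#' @param path GeoJSON file.
#' @return Tibble: `level`, `area_km2`, `polygons` (list of rings with
#'   hole attributes).
#' @export
read_isopleths <- function(path) {
  fc <- jsonlite::read_json(path)
  rows <- lapply(fc$features, function(f) {
    rings <- list()
    for (poly in f$geometry$coordinates) {
      for (ri in seq_along(poly)) {
        m <- do.call(rbind, lapply(poly[[ri]], function(p) c(p[[1]], p[[2]])))
        attr(m, "hole") <- ri > 1
        rings[[length(rings) + 1]] <- m
      }
    }
    tibble::tibble(level = f$properties$level,
                   area_km2 = f$properties$area_km2,
                   polygons = list(rings))
  })
  if (length(rows) == 0) {
    return(tibble::tibble(level = numeric(0), area_km2 = numeric(0),
                          polygons = list()))
  }
  dplyr::bind_rows(rows)
}

#' Write the coast geometry to GeoJSON
#'
#' @param coast A [coast_geometry()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_coast_geojson <- function(coast, path) {
  feat <- function(name, ring) {
    list(type = "Feature", properties = list(name = name),
         geometry = list(type = "Polygon", coordinates = list(.ring_coords(ring))))
  }
  fc <- list(type = "FeatureCollection",
             features = list(feat("island", coast$island),
                             feat("mainland", coast$mainland),
                             feat("exclusion_1nm", coast$exclusion),
                             feat("buffer", coast$buffer)))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
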