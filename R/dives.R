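# Dive detection from 1 Hz depth traces, surface-interval bookkeeping,
# dive--fix linking, and depth-use summaries.

#' Detect dive events in a depth trace
#'
#' A dive is a maximal run of consecutive samples with depth at or above
#' `min_depth` whose length reaches `min_duration` seconds at the series'
#' sampling rate. Max and mean depth are computed over the run. Detection
#' requires a uniform series: any gap handling must happen upstream (gaps
#' conservatively break dive runs when traces are split at them).
#'
#' @param series A `sensor_series` (see [render_sensors()]) or a data frame
#'   with columns `time` (POSIXct) and `depth` (m) sampled uniformly.
#' @param min_depth Depth threshold (m, default 0.1).
#' @param min_duration Minimum dive duration (s, default 5).
#' @return Tibble: `bird`, `start`, `end` (POSIXct UTC), `duration_s`,
#'   `max_depth_m`, `mean_depth_m`.
#' @export
detect_dives <- function(series, min_depth = 0.1, min_duration = 5) {
  stopifnot(min_depth > 0, min_duration > 0)
  if (inherits(series, "sensor_series")) {
    depth <- series$depth
    t0 <- as.numeric(series$start)
    rate <- series$rate
    bird <- series$bird
  } else {
    stopifnot(all(c("time", "depth") %in% names(series)))
    tt <- as.numeric(series$time)
    if (length(tt) > 1) {
      dt <- diff(tt)
      if (any(abs(dt - dt[1]) > 1e-6)) {
        stop("non-uniform sampling: split the series at gaps before dive detection")
      }
      rate <- 1 / dt[1]
    } else {
      rate <- 1
    }
    depth <- series$depth
    t0 <- tt[1]
    bird <- if ("bird" %in% names(series)) series$bird[1] else NA_character_
  }
  if (!all(is.finite(depth))) stop("depth trace contains non-finite values")

  r <- rle(depth >= min_depth)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  keep <- r$values & r$lengths >= ceiling(min_duration * rate)
  starts_i <- starts_i[keep]; ends_i <- ends_i[keep]
  n <- length(starts_i)
  maxd <- meand <- numeric(n)
  for (i in seq_len(n)) {
    seg <- depth[starts_i[i]:ends_i[i]]
    maxd[i] <- max(seg); meand[i] <- mean(seg)
  }
  tibble::tibble(
    bird = rep(bird, n),
    start = as.POSIXct(t0 + (starts_i - 1L) / rate, origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(t0 + ends_i / rate, origin = "1970-01-01", tz = "UTC"),
    duration_s = (ends_i - starts_i + 1L) / rate,
    max_depth_m = maxd, mean_depth_m = meand)
}

#' Build surface intervals between consecutive dives
#'
#' The non-diving time of a deployment is partitioned into n + 1 surface
#' intervals for n dives (including the leading and trailing interval).
#' Each GPS fix is assigned to exactly one interval; fixes whose timestamp
#' falls inside a dive are physically implausible and are dropped with a
#' warning.
#'
#' @param dives Tibble from [detect_dives()] (one bird), time-ordered and
#'   non-overlapping.
#' @param span Length-2 POSIXct/numeric: start and end of the series.
#' @param fixes Tibble with columns `time`, `lon`, `lat` (one bird).
#' @return Tibble: `interval`, `start`, `end`, `n_fixes`, and a list-column
#'   `fixes` with the member fixes in time order.
#' @export
build_surface_intervals <- function(dives, span, fixes = NULL) {
  s0 <- as.numeric(span[1]); s1 <- as.numeric(span[2])
  ds <- as.numeric(dives$start); de <- as.numeric(dives$end)
  n <- length(ds)
  if (n > 1 && any(ds[-1] < de[-n])) stop("overlapping dives")
  if (n > 0 && (ds[1] < s0 || de[n] > s1)) stop("dives outside the series span")
  int_start <- c(s0, de)
  int_end <- c(ds, s1)

  fx_list <- rep(list(NULL), n + 1)
  n_rejected <- 0L
  if (!is.null(fixes) && nrow(fixes) > 0) {
    ft <- as.numeric(fixes$time)
    in_dive <- rep(FALSE, length(ft))
    if (n > 0) {
      idx <- findInterval(ft, ds)
      in_dive <- idx >= 1 & ft < de[pmax(idx, 1)]
    }
    n_rejected <- sum(in_dive)
    if (n_rejected > 0) {
      warning(sprintf("%d fix(es) timestamped inside a dive were dropped", n_rejected))
    }
    ok <- !in_dive & ft >= s0 & ft <= s1
    iv <- findInterval(ft[ok], int_start)
    fx <- fixes[ok, , drop = FALSE]
    for (k in unique(iv)) fx_list[[k]] <- fx[iv == k, , drop = FALSE]
  }
  tibble::tibble(
    interval = seq_len(n + 1),
    start = as.POSIXct(int_start, origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(int_end, origin = "1970-01-01", tz = "UTC"),
    n_fixes = vapply(fx_list, function(f) if (is.null(f)) 0L else nrow(f), integer(1)),
    fixes = fx_list)
}

#' Link dives to GPS fixes via the preceding surface interval
#'
#' Each dive is assigned the temporally last fix of the surface interval
#' immediately preceding it; dives whose preceding interval holds no fix
#' remain unlocated (`lon`/`lat` NA).
#'
#' @param dives Tibble from [detect_dives()] (one bird).
#' @param intervals Tibble from [build_surface_intervals()] built from the
#'   same dive list.
#' @return `dives` with columns `lon`, `lat`, `fix_time` added.
#' @export
link_dives <- function(dives, intervals) {
  n <- nrow(dives)
  if (nrow(intervals) != n + 1) {
    stop("intervals were not built from this dive list (count mismatch)")
  }
  lon <- lat <- rep(NA_real_, n)
  ftime <- rep(as.POSIXct(NA, tz = "UTC"), n)
  for (i in seq_len(n)) {
    fx <- intervals$fixes[[i]]  # interval i precedes dive i
    if (!is.null(fx) && nrow(fx) > 0) {
      j <- which.max(as.numeric(fx$time))
      lon[i] <- fx$lon[j]; lat[i] <- fx$lat[j]; ftime[i] <- fx$time[j]
    }
  }
  dplyr::mutate(dives, lon = lon, lat = lat, fix_time = ftime)
}

#' Depth-frequency histogram of dives
#'
#' Bins per-dive maximum depth into half-open classes `[k*w, (k+1)*w)`.
#'
#' @param dives Tibble with a `max_depth_m` column.
#' @param bin_width Class width (m, default 5).
#' @return Object of class `depth_histogram`: tibble `bin_lower`,
#'   `bin_upper`, `count`, with attributes `bin_width` and `total`.
#' @export
depth_histogram <- function(dives, bin_width = 5) {
  stopifnot(bin_width > 0)
  d <- dives$max_depth_m
  if (length(d) == 0) {
    out <- tibble::tibble(bin_lower = numeric(0), bin_upper = numeric(0),
                          count = integer(0))
  } else {
    k <- floor(d / bin_width)
    tab <- table(factor(k, levels = 0:max(k)))
    out <- tibble::tibble(bin_lower = as.numeric(names(tab)) * bin_width,
                          bin_upper = (as.numeric(names(tab)) + 1) * bin_width,
                          count = as.integer(tab))
  }
  structure(out, bin_width = bin_width, total = length(d),
            class = c("depth_histogram", class(out)))
}

#' Share of dives at or above a depth threshold
#'
#' @param dives Tibble with `max_depth_m` (must be non-empty).
#' @param threshold Depth threshold (m).
#' @param above If TRUE report the share deeper than the threshold instead.
#' @return Percentage (0--100).
#' @export
depth_share <- function(dives, threshold = 30, above = FALSE) {
  d <- dives$max_depth_m
  if (length(d) == 0) stop("depth share undefined for an empty dive table")
  p <- mean(d <= threshold) * 100
  if (above) 100 - p else p
}
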