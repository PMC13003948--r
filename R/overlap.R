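# Fishery--seabird overlap: isopleth intersection areas and the
# cross-type pair correlation function with two edge corrections.

#' Overlap between penguin and fishery isopleths
#'
#' Intersects the post-erase cell masks of two isopleth sets fitted on the
#' same grid. Absolute overlap is the summed cell area of the
#' intersection; relative overlap expresses it as a percentage of the
#' penguin isopleth area. A sub-region ring (planar, projected metres)
#' restricts the penguin side, e.g. to the coastal core.
#'
#' @param penguin_iso,fishery_iso `isopleth_set` objects from
#'   [ud_isopleths()] on identical grids.
#' @param sub_ring Optional planar ring (two-column matrix, metres)
#'   restricting the penguin isopleth to a named sub-region.
#' @param sub_label Label for the sub-region column.
#' @return Tibble: `level`, `region`, `penguin_area`, `fishery_area`,
#'   `overlap`, `overlap_pct` (areas in the isopleths' units, km^2 when
#'   projected).
#' @export
kde_overlap <- function(penguin_iso, fishery_iso, sub_ring = NULL,
                        sub_label = "all") {
  gp <- attr(penguin_iso, "grid"); gf <- attr(fishery_iso, "grid")
  if (!isTRUE(all.equal(gp$x, gf$x)) || !isTRUE(all.equal(gp$y, gf$y))) {
    stop("isopleth sets were fitted on different grids; refit on a shared grid")
  }
  lv <- intersect(penguin_iso$level, fishery_iso$level)
  if (length(lv) == 0) stop("no common isopleth levels")
  unit_div <- if (is.null(gp$proj)) 1 else 1e6
  sub_mask <- NULL
  if (!is.null(sub_ring)) {
    centers <- as.matrix(expand.grid(x = gp$x, y = gp$y))
    sub_mask <- matrix(point_in_rings(centers, sub_ring),
                       length(gp$x), length(gp$y))
  }
  rows <- lapply(lv, function(L) {
    mp <- attr(penguin_iso, "masks")[[match(L, penguin_iso$level)]]
    mf <- attr(fishery_iso, "masks")[[match(L, fishery_iso$level)]]
    if (!is.null(sub_mask)) mp <- mp & sub_mask
    pa <- sum(gp$cell_area[mp]) / unit_div
    fa <- sum(gf$cell_area[mf]) / unit_div
    ov <- sum(gp$cell_area[mp & mf]) / unit_div
    tibble::tibble(level = L, region = sub_label,
                   penguin_area = pa, fishery_area = fa, overlap = ov,
                   overlap_pct = if (pa > 0) 100 * ov / pa else NA_real_)
  })
  dplyr::bind_rows(rows)
}

# ---- observation windows ----------------------------------------------------

#' Observation window for point-pattern statistics
#'
#' Either a rectangle (`xlim`/`ylim`) or a polygonal window given as one
#' or more planar rings (even-odd rule), rasterised at `cellsize` for
#' translation-correction set covariances and point-membership tests.
#'
#' @param xlim,ylim Rectangle bounds (m); ignored when `rings` is given.
#' @param rings A ring matrix or list of rings (projected metres),
#'   combined by the even-odd rule.
#' @param exclude Optional list of rings removed from the window (e.g.
#'   land polygons inside an analysis buffer).
#' @param cellsize Raster resolution for polygonal windows (m).
#' @return Object of class `pcf_window` with an `area` element (m^2).
#' @export
pcf_window <- function(xlim = NULL, ylim = NULL, rings = NULL,
                       exclude = NULL, cellsize = 250) {
  if (is.null(rings)) {
    stopifnot(length(xlim) == 2, length(ylim) == 2,
              xlim[2] > xlim[1], ylim[2] > ylim[1])
    return(structure(list(type = "rect", xlim = xlim, ylim = ylim,
                          area = diff(xlim) * diff(ylim)),
                     class = "pcf_window"))
  }
  if (is.matrix(rings)) rings <- list(rings)
  bb <- do.call(rbind, rings)
  xlim <- range(bb[, 1]); ylim <- range(bb[, 2])
  xs <- seq(xlim[1] + cellsize / 2, xlim[2], by = cellsize)
  ys <- seq(ylim[1] + cellsize / 2, ylim[2], by = cellsize)
  centers <- as.matrix(expand.grid(x = xs, y = ys))
  mask <- rep(FALSE, nrow(centers))
  for (ring in rings) mask <- xor(mask, point_in_rings(centers, ring))
  if (!is.null(exclude)) {
    if (is.matrix(exclude)) exclude <- list(exclude)
    for (ring in exclude) mask <- mask & !point_in_rings(centers, ring)
  }
  mask <- matrix(mask, length(xs), length(ys))
  structure(list(type = "mask", xlim = xlim, ylim = ylim, xs = xs, ys = ys,
                 cellsize = cellsize, mask = mask,
                 area = sum(mask) * cellsize^2),
            class = "pcf_window")
}

#' @export
print.pcf_window <- function(x, ...) {
  cat(sprintf("<pcf_window> %s, area %.2f km2\n", x$type, x$area / 1e6))
  invisible(x)
}

# Window membership test.
.win_inside <- function(pts, w) {
  if (w$type == "rect") {
    pts[, 1] >= w$xlim[1] & pts[, 1] <= w$xlim[2] &
      pts[, 2] >= w$ylim[1] & pts[, 2] <= w$ylim[2]
  } else {
    ix <- round((pts[, 1] - w$xs[1]) / w$cellsize) + 1L
    iy <- round((pts[, 2] - w$ys[1]) / w$cellsize) + 1L
    ok <- ix >= 1L & ix <= length(w$xs) & iy >= 1L & iy <= length(w$ys)
    res <- logical(nrow(pts))
    res[ok] <- w$mask[cbind(ix[ok], iy[ok])]
    res
  }
}

# Isotropic edge weight: reciprocal fraction of the circle of radius d
# centred at u lying inside the window, evaluated on a uniform angular
# grid of n_angles points (part of the estimator's definition).
.edge_iso <- function(u, d, w, n_angles) {
  th <- (seq_len(n_angles) - 0.5) * 2 * pi / n_angles
  ct <- cos(th); st <- sin(th)
  np <- nrow(u)
  frac <- numeric(np)
  chunk <- max(1L, floor(4e6 / n_angles))
  for (i0 in seq(1, np, by = chunk)) {
    ii <- i0:min(i0 + chunk - 1L, np)
    cx <- u[ii, 1] + outer(d[ii], ct)   # rows: pairs, cols: angles
    cy <- u[ii, 2] + outer(d[ii], st)
    ins <- .win_inside(cbind(as.vector(cx), as.vector(cy)), w)
    frac[ii] <- rowMeans(matrix(ins, nrow = length(ii)))
  }
  1 / pmax(frac, 1 / n_angles)
}

# Translation edge weight: |W| / |W intersect (W shifted by v - u)|.
.edge_trans <- function(u, v, w) {
  t <- v - u
  np <- nrow(t)
  if (w$type == "rect") {
    a <- diff(w$xlim); b <- diff(w$ylim)
    ov <- pmax(a - abs(t[, 1]), 0) * pmax(b - abs(t[, 2]), 0)
  } else {
    cs <- w$cellsize
    nx <- length(w$xs); ny <- length(w$ys)
    ov <- numeric(np)
    for (i in seq_len(np)) {
      sx <- round(t[i, 1] / cs); sy <- round(t[i, 2] / cs)
      ax <- max(1, 1 - sx):min(nx, nx - sx)
      ay <- max(1, 1 - sy):min(ny, ny - sy)
      if (length(ax) == 0 || length(ay) == 0) { ov[i] <- 0; next }
      ov[i] <- sum(w$mask[ax, ay, drop = FALSE] &
                     w$mask[ax + sx, ay + sy, drop = FALSE]) * cs^2
    }
  }
  w$area / pmax(ov, 1e-12)
}

#' Cross-type pair correlation function
#'
#' Kernel estimator of g_ij(r) between two point patterns in a common
#' window:
#' g(r) = sum over (u in i, v in j) of e(u, v) k_bw(r - |u - v|) /
#' (2 pi r lambda_i lambda_j |W|), with edge correction e either Ripley's
#' isotropic weight (reciprocal in-window circle fraction, angular grid of
#' `n_angles`) or the translation weight |W| / |W intersect (W + v - u)|.
#' Smoothing uses an Epanechnikov kernel with Stoyan-rule bandwidth
#' 0.15 / sqrt(lambda_j) by default.
#'
#' @param points_i,points_j Two-column planar coordinate matrices (m);
#'   both patterns must lie inside the window and have at least 2 points.
#' @param window A [pcf_window()].
#' @param r Distance grid (m); strictly positive.
#' @param corrections Subset of `c("isotropic", "translation")`.
#' @param bw Smoothing bandwidth (m); default `0.15 / sqrt(lambda_j)`.
#' @param n_angles Angular resolution of the isotropic correction.
#' @return Tibble of class `cross_pcf`: `r`, `g_iso` and/or `g_trans`,
#'   with intensities, window area, and bandwidth as attributes.
#' @export
cross_pcf <- function(points_i, points_j, window,
                      r = seq(100, 10000, by = 100),
                      corrections = c("isotropic", "translation"),
                      bw = NULL, n_angles = 512) {
  Pi <- .as_coord_matrix(points_i); Pj <- .as_coord_matrix(points_j)
  if (nrow(Pi) < 2 || nrow(Pj) < 2) stop("each pattern needs at least 2 points")
  if (any(r <= 0)) stop("r grid must be strictly positive (r = 0 excluded)")
  if (!all(.win_inside(Pi, window)) || !all(.win_inside(Pj, window))) {
    stop("all points must lie inside the window")
  }
  corrections <- match.arg(corrections, several.ok = TRUE)
  area <- window$area
  lam_i <- nrow(Pi) / area; lam_j <- nrow(Pj) / area
  if (is.null(bw)) bw <- 0.15 / sqrt(lam_j)

  # pairwise distances, keeping pairs that can touch the r grid
  dx <- outer(Pi[, 1], Pj[, 1], "-")
  dy <- outer(Pi[, 2], Pj[, 2], "-")
  d <- sqrt(dx^2 + dy^2)
  keep <- which(d > 1e-9 & d <= max(r) + bw, arr.ind = TRUE)
  du <- Pi[keep[, 1], , drop = FALSE]
  dv <- Pj[keep[, 2], , drop = FALSE]
  dd <- d[keep]

  e_iso <- if ("isotropic" %in% corrections) .edge_iso(du, dd, window, n_angles) else NULL
  e_tr <- if ("translation" %in% corrections) .edge_trans(du, dv, window) else NULL

  epan <- function(u) ifelse(abs(u) <= bw, 0.75 * (1 - (u / bw)^2) / bw, 0)
  denom <- 2 * pi * r * lam_i * lam_j * area
  g_iso <- g_trans <- NULL
  if (!is.null(e_iso)) {
    g_iso <- vapply(seq_along(r), function(k)
      sum(e_iso * epan(r[k] - dd)) / denom[k], numeric(1))
  }
  if (!is.null(e_tr)) {
    g_trans <- vapply(seq_along(r), function(k)
      sum(e_tr * epan(r[k] - dd)) / denom[k], numeric(1))
  }
  out <- tibble::tibble(r = r)
  if (!is.null(g_iso)) out$g_iso <- g_iso
  if (!is.null(g_trans)) out$g_trans <- g_trans
  structure(out, lambda_i = lam_i, lambda_j = lam_j, area = area, bw = bw,
            n_i = nrow(Pi), n_j = nrow(Pj), n_angles = n_angles,
            class = c("cross_pcf", class(out)))
}

#' Summarise a cross-PCF curve
#'
#' Reports the curve's peak (arg-max) and the distance range over which it
#' exceeds a clustering threshold.
#'
#' @param curve A `cross_pcf` tibble.
#' @param correction Which correction column to summarise.
#' @param threshold Clustering threshold on g.
#' @return Tibble: `correction`, `peak_g`, `peak_r`, `has_peak` (peak
#'   exceeds threshold), `r_above_min`, `r_above_max` (NA when the curve
#'   never exceeds the threshold).
#' @export
pcf_summary <- function(curve, correction = c("isotropic", "translation"),
                        threshold = 1.5) {
  correction <- match.arg(correction)
  col <- if (correction == "isotropic") "g_iso" else "g_trans"
  if (!col %in% names(curve)) stop(sprintf("curve has no %s column", col))
  g <- curve[[col]]; r <- curve$r
  i <- which.max(g)
  above <- which(g > threshold)
  tibble::tibble(correction = correction, peak_g = g[i], peak_r = r[i],
                 has_peak = g[i] > threshold,
                 r_above_min = if (length(above)) r[min(above)] else NA_real_,
                 r_above_max = if (length(above)) r[max(above)] else NA_real_)
}
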