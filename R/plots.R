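# ggplot2 presentation layer.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.utilisation_distribution <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x / 1000, y = .data$y / 1000,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(density ~ (m^-2))) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (km)", y = "northing (km)") +
    ggplot2::theme_minimal()
}

#' @export
tidy.utilisation_distribution <- function(x, ...) {
  tibble::tibble(x = rep(x$x, times = length(x$y)),
                 y = rep(x$y, each = length(x$x)),
                 density = as.vector(x$z))
}

#' @export
tidy.isopleth_set <- function(x, ...) {
  tibble::as_tibble(x[, c("level", "threshold", "mass", "area", "area_post")])
}

#' @export
autoplot.isopleth_set <- function(object, ...) {
  rows <- list()
  for (k in seq_len(nrow(object))) {
    for (i in seq_along(object$polygons[[k]])) {
      r <- object$polygons[[k]][[i]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        level = factor(object$level[k]), ring = sprintf("%d_%d", k, i),
        lon = r[, 1], lat = r[, 2])
    }
  }
  df <- dplyr::bind_rows(rows)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   group = .data$ring,
                                   colour = .data$level)) +
    ggplot2::geom_path() +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "longitude", y = "latitude", colour = "isopleth") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cross_pcf <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), -"r",
                            names_to = "correction", values_to = "g")
  df$correction <- c(g_iso = "isotropic", g_trans = "translation")[df$correction]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r / 1000, y = .data$g,
                                   linetype = .data$correction)) +
    ggplot2::geom_hline(yintercept = 1, colour = "red", linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (km)", y = expression(g[ij](r))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.depth_histogram <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_lower + attr(object, "bin_width") / 2,
                                   y = .data$count)) +
    ggplot2::geom_col(width = attr(object, "bin_width") * 0.9) +
    ggplot2::scale_x_reverse() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "maximum dive depth (m)", y = "dives") +
    ggplot2::theme_minimal()
}
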