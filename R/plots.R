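# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

map_theme <- function() {
  ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid.minor = ggplot2::element_blank())
}

#' Plot a suitability map
#'
#' Non-analogue cells (any predictor outside its training range) are
#' overlaid with dots.
#'
#' @param object A `pn_suitability`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pn_suitability <- function(object, ...) {
  df <- as_tibble.pn_raster(object$raster)
  spec <- object$raster$spec
  na_cells <- which(object$non_analogue, arr.ind = TRUE)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "suitability", limits = c(0, 1)) +
    ggplot2::coord_fixed() + map_theme() +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  subtitle = sprintf("mode: %s, scale: %s", object$mode,
                                     object$scale))
  if (nrow(na_cells))
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(lon = lon_centers(spec)[na_cells[, 2]],
                            lat = lat_centers(spec)[na_cells[, 1]]),
      ggplot2::aes(x = .data$lon, y = .data$lat), inherit.aes = FALSE,
      shape = 20, size = 0.4, colour = "grey30")
  p
}

#' Plot a taphofacies classification
#'
#' @param object A `pn_taphofacies`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pn_taphofacies <- function(object, ...) {
  spec <- object$spec
  df <- tibble::tibble(
    lon = rep(lon_centers(spec), each = spec$n_rows),
    lat = rep(lat_centers(spec), times = spec$n_cols),
    class = c("low", "high")[as.vector(object$class)])
  df <- df[!is.na(df$class), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(high = "#b2182b", low = "#2166ac"),
                               name = object$parameter) +
    ggplot2::coord_fixed() + map_theme() +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  subtitle = sprintf("break: %.4g %s", object$break_value,
                                     object$units))
}

#' Plot a hot/cold-spot classification
#'
#' @param object A `pn_spots`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pn_spots <- function(object, ...) {
  spec <- object$z$spec
  df <- tibble::tibble(
    lon = rep(lon_centers(spec), each = spec$n_rows),
    lat = rep(lat_centers(spec), times = spec$n_cols),
    class = c("cold", "neither", "hot")[as.vector(object$class)])
  df <- df[!is.na(df$class), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(hot = "#b2182b", cold = "#2166ac",
                                          neither = "grey85"),
                               name = "Gi* class") +
    ggplot2::coord_fixed() + map_theme() +
    ggplot2::labs(x = "Longitude", y = "Latitude")
}

#' Habitat-area trajectories across time bins
#'
#' Line plot of the per-bin habitat areas produced by [run_enm_stage()],
#' faceted by region, one line per threshold.
#'
#' @param areas The `areas` tibble from [run_enm_stage()].
#' @return A ggplot.
#' @export
plot_habitat_areas <- function(areas) {
  ggplot2::ggplot(areas,
                  ggplot2::aes(x = .data$train_bin, y = .data$area_km2,
                               colour = factor(.data$threshold),
                               group = .data$threshold)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_grid(.data$clade ~ .data$region, scales = "free_y") +
    ggplot2::scale_colour_brewer(palette = "Dark2", name = "threshold") +
    ggplot2::labs(x = NULL, y = expression(Habitat~area~(km^2))) +
    ggplot2::theme_minimal()
}
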