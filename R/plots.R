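#' Plot a temperature field
#'
#' Raster map of a gridded SST field; masked (land) cells are blank.
#'
#' @param object A [temperature_field()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.temperature_field <- function(object, ...) {
  grid <- expand.grid(lon = object$lon_axis, lat = object$lat_axis,
                      KEEP.OUT.ATTRS = FALSE)
  grid$sst <- as.vector(object$values)
  ggplot2::ggplot(grid[!is.na(grid$sst), ],
                  ggplot2::aes(x = .data$lon, y = .data$lat,
                               fill = .data$sst)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "SST (°C)",
                                  option = "plasma") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude (°)", y = "Latitude (°)",
                  title = paste("Summer SST:", object$geography_tag,
                                object$scenario_tag)) +
    ggplot2::theme_minimal()
}

#' Thermal bias across the occupancy-response gradient
#'
#' Box plots of species thermal bias per ordered response level, with
#' jittered points, the standard diagnostic for the bias-response
#' gradient.
#'
#' @param records Response records with `thermal_bias` and `level` (or
#'   `level_pooled`).
#' @param by_phase Facet by climate `phase` when that column is present.
#' @return A ggplot object.
#' @export
plot_bias_gradient <- function(records, by_phase = FALSE) {
  lev_col <- if ("level_pooled" %in% names(records)) {
    "level_pooled"
  } else {
    "level"
  }
  nm <- names(response_levels())
  dat <- dplyr::mutate(
    records,
    response_f = factor(nm[.data[[lev_col]]], levels = nm))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$response_f,
                                         y = .data$thermal_bias)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.3, size = 0.8) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = NA,
                          colour = "grey20") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2,
                        colour = "grey50") +
    ggplot2::labs(x = "Occupancy response",
                  y = "Thermal bias (°C)") +
    ggplot2::theme_minimal()
  if (by_phase && "phase" %in% names(dat)) {
    p <- p + ggplot2::facet_wrap(~phase)
  }
  p
}

#' Context slopes against regional warming magnitude
#'
#' @param x A `slope_warming_fit` from [slope_vs_warming()].
#' @param ... Unused.
#' @return A ggplot object: per-context slopes with error bars, point size
#'   by species count, and the inverse-variance-weighted regression line.
#' @export
autoplot.slope_warming_fit <- function(x, ...) {
  ggplot2::ggplot(x$data,
                  ggplot2::aes(x = .data$delta_t, y = .data$slope)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$slope - .data$se,
                                        ymax = .data$slope + .data$se),
                           width = 0, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_species)) +
    ggplot2::geom_abline(intercept = coef(x$model)[1],
                         slope = coef(x$model)[2]) +
    ggplot2::labs(x = "Regional temperature change (°C)",
                  y = "Bias difference per response level (°C)",
                  size = "Species") +
    ggplot2::theme_minimal()
}
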