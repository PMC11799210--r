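#' Gridded sea-surface-temperature field
#'
#' Container for one regular lon-lat grid of summer mean sea-surface
#' temperature (degrees C), cell-center registered, with `NA` marking
#' land-masked cells.
#'
#' @param lon_axis,lat_axis Strictly monotone increasing numeric vectors of
#'   cell-center coordinates (decimal degrees).
#' @param values Numeric matrix of SST, `length(lon_axis)` rows by
#'   `length(lat_axis)` columns; `NA` = land.
#' @param geography_tag,scenario_tag Free-form labels (e.g. paleogeography
#'   and pCO2 scenario identifiers).
#' @return An object of class `temperature_field`.
#' @examples
#' f <- temperature_field(seq(-10, 10, 5), seq(20, 40, 5),
#'                        matrix(20, 5, 5))
#' @export
temperature_field <- function(lon_axis, lat_axis, values,
                              geography_tag = NA_character_,
                              scenario_tag = NA_character_) {
  lon_axis <- as.numeric(lon_axis)
  lat_axis <- as.numeric(lat_axis)
  values <- as.matrix(values)
  stopifnot(all(diff(lon_axis) > 0), all(diff(lat_axis) > 0),
            nrow(values) == length(lon_axis),
            ncol(values) == length(lat_axis))
  finite <- values[is.finite(values)]
  if (length(finite) > 0 && (min(finite) < -5 || max(finite) > 60)) {
    warning("SST values outside plausibility window [-5, 60] degrees C")
  }
  structure(list(lon_axis = lon_axis, lat_axis = lat_axis, values = values,
                 geography_tag = geography_tag, scenario_tag = scenario_tag),
            class = "temperature_field")
}

#' @export
print.temperature_field <- function(x, ...) {
  cat("temperature_field: ", length(x$lon_axis), " x ", length(x$lat_axis),
      " cells; lon [", min(x$lon_axis), ", ", max(x$lon_axis),
      "], lat [", min(x$lat_axis), ", ", max(x$lat_axis), "]\n", sep = "")
  cat("masked cells: ", sum(is.na(x$values)), "; geography: ",
      x$geography_tag, "; scenario: ", x$scenario_tag, "\n", sep = "")
  invisible(x)
}

#' Read / write a temperature field as gridded CSV
#'
#' Long-format CSV with columns `lon`, `lat`, `sst` (one row per grid cell;
#' masked cells may be omitted or carry empty `sst`). The grid is
#' reconstructed from the unique sorted coordinates.
#'
#' @param path CSV file path.
#' @param geography_tag,scenario_tag Labels attached to the field on read.
#' @return `read_field_csv()` returns a [temperature_field()];
#'   `write_field_csv()` returns `path` invisibly.
#' @export
read_field_csv <- function(path, geography_tag = NA_character_,
                           scenario_tag = NA_character_) {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("lon", "lat", "sst") %in% names(dat)))
  lon_axis <- sort(unique(dat$lon))
  lat_axis <- sort(unique(dat$lat))
  values <- matrix(NA_real_, length(lon_axis), length(lat_axis))
  values[cbind(match(dat$lon, lon_axis), match(dat$lat, lat_axis))] <- dat$sst
  temperature_field(lon_axis, lat_axis, values,
                    geography_tag = geography_tag,
                    scenario_tag = scenario_tag)
}

#' @rdname read_field_csv
#' @param field A [temperature_field()].
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "temperature_field"))
  grid <- expand.grid(lon = field$lon_axis, lat = field$lat_axis,
                      KEEP.OUT.ATTRS = FALSE)
  grid$sst <- as.vector(field$values)
  readr::write_csv(tibble::as_tibble(grid), path, progress = FALSE)
  invisible(path)
}

cell_of <- function(axis, x) {
  # containing cell for cell-center registered regular axis
  step <- if (length(axis) > 1) diff(axis)[1] else 1
  edges <- c(axis - step / 2, axis[length(axis)] + step / 2)
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[i < 1 | i > length(axis)] <- NA_integer_
  i
}

#' Sample a temperature field at point coordinates
#'
#' Returns the SST of the grid cell containing each point. If that cell is
#' land-masked, the nearest unmasked cell (great-circle distance between
#' cell centers) within a window of `max_search_cells` cells in each axis
#' direction is used; ties are broken by smaller |delta lat|, then smaller
#' |delta lon|, then the westernmost and southernmost candidate (so the
#' result is fully deterministic even for symmetric neighbours). Points
#' whose window holds no unmasked cell, or that fall outside the grid,
#' yield `NA`.
#'
#' @param field A [temperature_field()].
#' @param lon,lat Numeric vectors of point coordinates (degrees).
#' @param max_search_cells Integer search radius in cells for the
#'   nearest-unmasked fallback; default 2.
#' @return Numeric vector of SST (degrees C), `NA` where unsampleable.
#' @export
sample_temperature <- function(field, lon, lat, max_search_cells = 2L) {
  stopifnot(inherits(field, "temperature_field"),
            length(lon) == length(lat))
  ci <- cell_of(field$lon_axis, lon)
  cj <- cell_of(field$lat_axis, lat)
  out <- rep(NA_real_, length(lon))
  ok <- !is.na(ci) & !is.na(cj)
  direct <- ok & !is.na(field$values[cbind(pmax(ci, 1), pmax(cj, 1))])
  out[direct] <- field$values[cbind(ci[direct], cj[direct])]
  for (p in which(ok & !direct)) {
    out[p] <- nearest_unmasked(field, ci[p], cj[p], max_search_cells)
  }
  out
}

nearest_unmasked <- function(field, i, j, radius) {
  ni <- length(field$lon_axis); nj <- length(field$lat_axis)
  ii <- max(1, i - radius):min(ni, i + radius)
  jj <- max(1, j - radius):min(nj, j + radius)
  cand <- expand.grid(ci = ii, cj = jj, KEEP.OUT.ATTRS = FALSE)
  vals <- field$values[cbind(cand$ci, cand$cj)]
  cand <- cand[!is.na(vals), , drop = FALSE]
  if (nrow(cand) == 0) return(NA_real_)
  here <- c(field$lon_axis[i], field$lat_axis[j])
  d <- geosphere::distHaversine(
    here, cbind(field$lon_axis[cand$ci], field$lat_axis[cand$cj]))
  dlat <- abs(field$lat_axis[cand$cj] - here[2])
  dlon <- abs(field$lon_axis[cand$ci] - here[1])
  # distances rounded to micrometers so that geometrically symmetric
  # candidates tie exactly and fall through to the deterministic breaks
  best <- order(round(d, 6), dlat, dlon,
                field$lon_axis[cand$ci], field$lat_axis[cand$cj])[1]
  field$values[cand$ci[best], cand$cj[best]]
}

#' Bilinear downscaling of a temperature field
#'
#' Interpolates a coarse field onto finer target axes using the four
#' surrounding coarse cell centers. Weights of masked neighbours are
#' dropped and the remaining weights renormalized; a target cell with all
#' four neighbours masked is masked. Because the weights are non-negative
#' and sum to one, the result never overshoots the coarse field's range.
#'
#' @param coarse A [temperature_field()].
#' @param target_lon_axis,target_lat_axis Strictly increasing numeric axes
#'   within the coarse field's bounding box.
#' @return A [temperature_field()] on the target axes, tags carried over.
#' @export
downscale_bilinear <- function(coarse, target_lon_axis, target_lat_axis) {
  stopifnot(inherits(coarse, "temperature_field"))
  tl <- as.numeric(target_lon_axis); tt <- as.numeric(target_lat_axis)
  stopifnot(all(diff(tl) > 0), all(diff(tt) > 0),
            min(tl) >= min(coarse$lon_axis), max(tl) <= max(coarse$lon_axis),
            min(tt) >= min(coarse$lat_axis), max(tt) <= max(coarse$lat_axis))
  lx <- coarse$lon_axis; ly <- coarse$lat_axis
  i0 <- pmin(pmax(findInterval(tl, lx), 1), length(lx) - 1)
  j0 <- pmin(pmax(findInterval(tt, ly), 1), length(ly) - 1)
  fx <- (tl - lx[i0]) / (lx[i0 + 1] - lx[i0])
  fy <- (tt - ly[j0]) / (ly[j0 + 1] - ly[j0])
  vals <- matrix(NA_real_, length(tl), length(tt))
  for (a in seq_along(tl)) {
    v00 <- coarse$values[i0[a], j0]
    v10 <- coarse$values[i0[a] + 1, j0]
    v01 <- coarse$values[i0[a], j0 + 1]
    v11 <- coarse$values[i0[a] + 1, j0 + 1]
    w00 <- (1 - fx[a]) * (1 - fy); w10 <- fx[a] * (1 - fy)
    w01 <- (1 - fx[a]) * fy;       w11 <- fx[a] * fy
    num <- ifelse(is.na(v00), 0, w00 * v00) +
      ifelse(is.na(v10), 0, w10 * v10) +
      ifelse(is.na(v01), 0, w01 * v01) +
      ifelse(is.na(v11), 0, w11 * v11)
    den <- ifelse(is.na(v00), 0, w00) + ifelse(is.na(v10), 0, w10) +
      ifelse(is.na(v01), 0, w01) + ifelse(is.na(v11), 0, w11)
    vals[a, ] <- ifelse(den > 0, num / den, NA_real_)
  }
  temperature_field(tl, tt, vals,
                    geography_tag = coarse$geography_tag,
                    scenario_tag = coarse$scenario_tag)
}

#' Compare two temperature fields
#'
#' Spearman rank correlation and root-mean-square difference over jointly
#' unmasked cells, plus the cell-wise difference map (a minus b, mask
#' union). Fields must share axes; resample (e.g. [downscale_bilinear()])
#' first otherwise. The RMSE here is the root of the mean squared
#' difference, not mean-centered; pass `centered = TRUE` for the
#' residual-standard-deviation variant.
#'
#' @param a,b [temperature_field()] objects on identical axes.
#' @param centered If `TRUE`, subtract the mean difference before the RMS.
#' @return A list: `rho`, `rmse`, `difference_map` (a `temperature_field`),
#'   `n_cells`.
#' @export
compare_fields <- function(a, b, centered = FALSE) {
  stopifnot(inherits(a, "temperature_field"),
            inherits(b, "temperature_field"))
  if (!isTRUE(all.equal(a$lon_axis, b$lon_axis)) ||
      !isTRUE(all.equal(a$lat_axis, b$lat_axis))) {
    stop("fields must share identical axes; resample first", call. = FALSE)
  }
  both <- !is.na(a$values) & !is.na(b$values)
  if (sum(both) < 3) {
    stop("fewer than 3 jointly unmasked cells; comparison undefined",
         call. = FALSE)
  }
  da <- a$values[both]; db <- b$values[both]
  diffs <- da - db
  if (centered) diffs <- diffs - mean(diffs)
  diff_vals <- a$values - b$values
  diff_vals[!both] <- NA_real_
  diff_field <- structure(
    list(lon_axis = a$lon_axis, lat_axis = a$lat_axis, values = diff_vals,
         geography_tag = a$geography_tag,
         scenario_tag = paste0(a$scenario_tag, "-", b$scenario_tag)),
    class = "temperature_field")
  list(rho = cor(da, db, method = "spearman"),
       rmse = sqrt(mean(diffs^2)),
       difference_map = diff_field,
       n_cells = sum(both))
}

#' Default pCO2 scenario table
#'
#' One row per time bin with the main and secondary atmospheric pCO2
#' scenario (ppm) used to select the temperature field for that bin, and
#' the paleogeography tag. Reflects proxy-constrained estimates across the
#' late Pliensbachian to middle Toarcian: low pCO2 in the cool late
#' Pliensbachian, a rise into the earliest Toarcian, a peak during the
#' anoxic-event subzone, then sustained warmth.
#'
#' @param path Optional YAML file with rows `time_bin`, `main_pco2_ppm`,
#'   `secondary_pco2_ppm`, `geography_tag` overriding the defaults.
#' @return Tibble: `time_bin`, `main_pco2_ppm`, `secondary_pco2_ppm`,
#'   `geography_tag`.
#' @export
scenario_table <- function(path = NULL) {
  if (!is.null(path)) {
    raw <- yaml::read_yaml(path)
    return(dplyr::bind_rows(lapply(raw, tibble::as_tibble)))
  }
  tibble::tibble(
    time_bin = c("Margaritatus", "Spinatum", "Tenuicostatum",
                 "Exaratum", "Falciferum", "Bifrons"),
    main_pco2_ppm = c(400, 400, 500, 1000, 750, 750),
    secondary_pco2_ppm = c(300, 300, 500, 1500, 1000, 750),
    geography_tag = "180Ma"
  )
}
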