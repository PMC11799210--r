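#' Species temperature indices (STI)
#'
#' Estimates each species' long-term thermal optimum as the central
#' tendency of the temperatures sampled at all of its occurrences, pooled
#' across every analysed time bin and region. The default estimator is the
#' median ("thermal median"); the mean is available as a sensitivity
#' option. Species whose occurrences carry no usable temperature are
#' excluded and counted in the `dropped_no_temperature` attribute.
#'
#' @param occurrences Tibble with columns `species` and `temperature`
#'   (degrees C, `NA` allowed).
#' @param method "median" (default) or "mean".
#' @return Tibble: `species`, `sti` (degrees C), `n_temps`, `temp_spread`
#'   (SD of the sampled temperatures, `NA` when `n_temps = 1`); attribute
#'   `dropped_no_temperature` holds the count of excluded species.
#' @examples
#' occ <- tibble::tibble(species = c("a", "a", "a"),
#'                       temperature = c(18, 20, 30))
#' species_sti(occ)
#' @export
species_sti <- function(occurrences, method = c("median", "mean")) {
  method <- match.arg(method)
  stopifnot(all(c("species", "temperature") %in% names(occurrences)))
  est <- if (method == "median") median else mean
  usable <- dplyr::filter(occurrences, !is.na(.data$temperature))
  dropped <- setdiff(unique(occurrences$species), unique(usable$species))
  out <- usable |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(sti = est(.data$temperature),
                     n_temps = dplyr::n(),
                     temp_spread = sd(.data$temperature),
                     .groups = "drop")
  attr(out, "dropped_no_temperature") <- length(dropped)
  out
}

#' Regional median temperature per time bin
#'
#' The ambient temperature of a region in a bin: the median over the
#' temperatures sampled at the occurrence paleocoordinates falling in that
#' region and bin. Each occurrence counts once by default; set
#' `locality_unique = TRUE` to collapse to unique coordinates first.
#'
#' @param occurrences Tibble with `region_id`, `time_bin`, `temperature`,
#'   and (if `locality_unique`) the coordinate columns in `coords`.
#' @param locality_unique Collapse duplicate localities before the median.
#' @param coords Coordinate columns used for locality collapsing.
#' @return Tibble: `region_id`, `time_bin`, `median_t`, `n_temps`.
#' @export
regional_median_temperature <- function(occurrences,
                                        locality_unique = FALSE,
                                        coords = c("paleo_lon_primary",
                                                   "paleo_lat_primary")) {
  stopifnot(all(c("region_id", "time_bin", "temperature") %in%
                  names(occurrences)))
  dat <- dplyr::filter(occurrences, !is.na(.data$temperature))
  if (locality_unique) {
    dat <- dplyr::distinct(
      dat, .data$region_id, .data$time_bin,
      .data[[coords[1]]], .data[[coords[2]]], .data$temperature)
  }
  dat |>
    dplyr::group_by(.data$region_id, .data$time_bin) |>
    dplyr::summarise(median_t = median(.data$temperature),
                     n_temps = dplyr::n(), .groups = "drop")
}

#' Thermal bias
#'
#' Difference between a thermal preference and the ambient temperature,
#' `preference - ambient`. The sign convention makes warm-adapted
#' immigrants positive: a species whose optimum is warmer than local
#' conditions has positive bias, one stranded in water warmer than its
#' optimum has negative bias. Vectorized.
#'
#' @param preference Thermal preference(s), degrees C (e.g. STI or CTI).
#' @param ambient Ambient temperature(s), degrees C (e.g. regional median).
#' @return Numeric vector of biases, degrees C.
#' @examples
#' thermal_bias(25, 22)   # +3: prefers warmer than ambient
#' thermal_bias(15, 22)   # -7: cold-adapted relative to ambient
#' @export
thermal_bias <- function(preference, ambient) {
  preference - ambient
}

#' Assemblage thermal preference and bias
#'
#' Community temperature index (CTI) and assemblage thermal bias for one
#' region-bin assemblage. The CTI is the median of the member species'
#' STIs; the assemblage bias is CTI minus the regional ambient temperature;
#' `bias_sd` is the standard deviation of member-level biases (used for
#' inverse-variance weighting of assemblage-level regressions). Optional
#' weighting towards cool- or warm-adapted members replaces the plain
#' median by a weighted median with weights `rank`-based on STI raised to
#' `exponent`.
#'
#' @param member_stis Numeric vector of member species' STIs (>= 1 value;
#'   >= 2 for a finite `bias_sd`).
#' @param ambient Regional median temperature, degrees C.
#' @param weighting "none" (default), "cool" or "warm".
#' @param exponent Weighting strength; default 1.
#' @return One-row tibble: `cti`, `bias`, `bias_sd`, `n_species`.
#' @examples
#' assemblage_bias(c(18, 20, 30), ambient = 24)
#' @export
assemblage_bias <- function(member_stis, ambient,
                            weighting = c("none", "cool", "warm"),
                            exponent = 1) {
  weighting <- match.arg(weighting)
  stis <- member_stis[!is.na(member_stis)]
  stopifnot(length(stis) >= 1, is.finite(ambient))
  cti <- if (weighting == "none") {
    median(stis)
  } else {
    r <- rank(stis, ties.method = "average")
    w <- if (weighting == "cool") {
      (length(stis) + 1 - r)^exponent
    } else {
      r^exponent
    }
    weighted_median(stis, w)
  }
  biases <- thermal_bias(stis, ambient)
  tibble::tibble(
    cti = cti,
    bias = cti - ambient,
    bias_sd = if (length(stis) >= 2) sd(biases) else NA_real_,
    n_species = length(stis)
  )
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  lo <- x[which(cw >= 0.5)[1]]
  hi <- x[which(cw > 0.5 - 1e-12)[1]]
  (lo + hi) / 2
}

#' Label climate phases on bin boundaries
#'
#' Attaches a climate-phase label to every boundary between consecutive
#' time bins. The default mapping for the default bin sequence runs cold
#' stasis, first warming pulse, second warming pulse (anoxic-event
#' interval), transitional, warm stasis; the warming-associated set is
#' `{warming_1, warming_2, transitional}`.
#'
#' @param tb A [time_bins()] object.
#' @param mapping Named character vector boundary-label -> phase. Must
#'   cover every boundary of `tb`. Default supplied for the default
#'   sequence.
#' @return Tibble: `boundary`, `bin_i`, `bin_i1`, `i`, `phase`,
#'   `warming_associated` (logical).
#' @export
label_phases <- function(tb = time_bins(), mapping = NULL) {
  bounds <- bin_boundaries(tb)
  if (is.null(mapping)) {
    default <- c("Margaritatus->Spinatum" = "cold_stasis",
                 "Spinatum->Tenuicostatum" = "warming_1",
                 "Tenuicostatum->Exaratum" = "warming_2",
                 "Exaratum->Falciferum" = "transitional",
                 "Falciferum->Bifrons" = "warm_stasis")
    if (!all(bounds$boundary %in% names(default))) {
      stop("no default phase mapping for this bin sequence; ",
           "supply `mapping`", call. = FALSE)
    }
    mapping <- default
  }
  missing <- setdiff(bounds$boundary, names(mapping))
  if (length(missing) > 0) {
    stop("phase mapping lacks boundaries: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  warming_set <- c("warming_1", "warming_2", "transitional")
  dplyr::mutate(bounds,
                phase = unname(mapping[.data$boundary]),
                warming_associated = .data$phase %in% warming_set)
}

#' Regional climate summary: medians, warming steps, phases
#'
#' Combines [regional_median_temperature()] with boundary deltas and phase
#' labels: for each region and boundary i -> i+1, `delta_t` is the change
#' in regional median temperature across the boundary.
#'
#' @param occurrences Occurrence tibble with `region_id`, `time_bin`,
#'   `temperature`.
#' @param tb A [time_bins()] object.
#' @param phase_mapping Optional mapping for [label_phases()].
#' @return A list: `medians` (region, bin, median_t, n_temps) and `deltas`
#'   (region, boundary, bin_i, bin_i1, median_t_i, median_t_i1, delta_t,
#'   phase, warming_associated).
#' @export
regional_climate <- function(occurrences, tb = time_bins(),
                             phase_mapping = NULL) {
  med <- regional_median_temperature(occurrences)
  phases <- label_phases(tb, phase_mapping)
  deltas <- tidyr::crossing(region_id = unique(med$region_id),
                            phases) |>
    dplyr::left_join(dplyr::rename(med, median_t_i = "median_t",
                                   n_i = "n_temps"),
                     by = c("region_id", "bin_i" = "time_bin")) |>
    dplyr::left_join(dplyr::rename(med, median_t_i1 = "median_t",
                                   n_i1 = "n_temps"),
                     by = c("region_id", "bin_i1" = "time_bin")) |>
    dplyr::mutate(delta_t = .data$median_t_i1 - .data$median_t_i) |>
    dplyr::select("region_id", "boundary", "bin_i", "bin_i1",
                  "median_t_i", "median_t_i1", "delta_t", "phase",
                  "warming_associated")
  list(medians = med, deltas = deltas)
}
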