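#' Pipeline configuration
#'
#' Collects the tunable parameters of an end-to-end run. Defaults follow
#' the standard analysis choices: ten spatial clusters, regions analyzable
#' at more than 25 occurrences per bin, slope meta-regression restricted
#' to contexts with at least 20 species, affinity tests at alpha 0.1,
#' median STI estimator, merged pooling (extinctions with extirpations,
#' originations with immigrations), and a +3 degree C prediction point.
#'
#' @param k_regions Spatial cluster count; default 10.
#' @param linkage Spatial clustering linkage; default "ward.D2".
#' @param min_occ_per_bin Analyzability threshold (strict >); default 25.
#' @param whitelist Region ids to force-retain.
#' @param scheme "two_timer" or "three_timer".
#' @param pooling "merged", "five_level" or "three_level".
#' @param sti_method "median" or "mean".
#' @param context Bias context-bin rule, see [attach_bias()].
#' @param coords "primary" (180 Ma rotation) or "secondary" (185 Ma).
#' @param min_species Context filter for [slope_vs_warming()]; default 20.
#' @param alpha Affinity-test significance level; default 0.1.
#' @param prediction_delta_t Warming magnitude for assemblage
#'   predictions; default +3.
#' @param max_search_cells Land-mask fallback radius for
#'   [sample_temperature()].
#' @param warming_only Restrict species-level model to warming-associated
#'   boundaries; default TRUE.
#' @param species_fixed Fixed-effect terms for [fit_species_model()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(k_regions = 10L,
                            linkage = "ward.D2",
                            min_occ_per_bin = 25L,
                            whitelist = integer(),
                            scheme = "two_timer",
                            pooling = "merged",
                            sti_method = "median",
                            context = "by_level",
                            coords = c("primary", "secondary"),
                            min_species = 20L,
                            alpha = 0.1,
                            prediction_delta_t = 3,
                            max_search_cells = 2L,
                            warming_only = TRUE,
                            species_fixed = "thermal_bias") {
  coords <- match.arg(coords)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full thermal-bias analysis pipeline
#'
#' Orchestrates: temperature sampling at occurrence paleocoordinates ->
#' spatial regionalization -> STI / regional climate / phase labels ->
#' occupancy-response classification with thermal bias -> assemblage
#' summaries -> species-level mixed model, per-context slopes with
#' warming meta-regression, and assemblage-level models with a prediction
#' at the configured warming. Deterministic given its inputs.
#'
#' @param occurrences Occurrence tibble (see [read_occurrences()] or
#'   [generate_world()]); flanking-bin rows supply the edge-relaxation
#'   presences.
#' @param fields Named list of [temperature_field()], one per analysed
#'   bin label.
#' @param range_table Global FAD/LAD table; computed from `occurrences`
#'   when `NULL`.
#' @param tb A [time_bins()] object.
#' @param config A [pipeline_config()].
#' @param phase_mapping Optional boundary -> phase mapping for
#'   [label_phases()].
#' @return A list of stage outputs: `occurrences` (with temperature and
#'   region), `regions`, `niches`, `climate`, `records` (classified, with
#'   bias, pooled), `assemblages`, `species_fit`, `slopes`, `slope_fit`
#'   (NULL if inestimable), `assemblage_fits`, `predictions`, `report`.
#' @export
run_pipeline <- function(occurrences, fields, range_table = NULL,
                         tb = time_bins(), config = pipeline_config(),
                         phase_mapping = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  missing_fields <- setdiff(tb$bins, names(fields))
  if (length(missing_fields) > 0) {
    stop("no temperature field for bin(s): ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  cxy <- if (config$coords == "primary") {
    c("paleo_lon_primary", "paleo_lat_primary")
  } else {
    c("paleo_lon_secondary", "paleo_lat_secondary")
  }
  n_input <- nrow(occurrences)

  # temperature sampling per analysed bin
  occ <- dplyr::mutate(occurrences, temperature = NA_real_)
  for (b in tb$bins) {
    sel <- which(occ$time_bin == b)
    if (length(sel) == 0) next
    occ$temperature[sel] <- sample_temperature(
      fields[[b]], occ[[cxy[1]]][sel], occ[[cxy[2]]][sel],
      max_search_cells = config$max_search_cells)
  }
  n_no_temp <- sum(is.na(occ$temperature) & occ$time_bin %in% tb$bins)

  # regionalization on pooled unique coordinates
  pts <- tibble::tibble(lon = occ[[cxy[1]]], lat = occ[[cxy[2]]])
  regions <- cluster_spatial(pts, k = config$k_regions,
                             linkage = config$linkage)
  occ$region_id <- NULL
  asg <- assign_regions(occ, regions, tb,
                        min_occ_per_bin = config$min_occ_per_bin,
                        whitelist = config$whitelist, coords = cxy)
  occ <- dplyr::left_join(occ, asg$assignment, by = "occurrence_id")
  analyzable <- asg$regions$region_id[asg$regions$analyzable]
  occ_a <- dplyr::filter(occ, .data$region_id %in% analyzable)

  # thermal metrics
  niches <- species_sti(
    dplyr::filter(occ_a, .data$time_bin %in% tb$bins),
    method = config$sti_method)
  climate <- regional_climate(occ_a, tb, phase_mapping)

  # range table from the full (global) dataset
  if (is.null(range_table)) {
    range_table <- compute_range_table(occurrences, tb)
  }

  # classification and bias
  records <- classify_occupancy(occ_a, range_table, tb,
                                scheme = config$scheme)
  n_unclassified <- attr(records, "n_unclassified")
  records <- attach_bias(records, niches, climate$medians,
                         context = config$context)
  n_no_bias <- attr(records, "n_dropped_no_bias")
  records <- records |>
    dplyr::left_join(
      dplyr::select(climate$deltas, "region_id", "boundary", "delta_t",
                    "phase", "warming_associated"),
      by = c("region_id", "boundary")) |>
    pool_levels(config$pooling)
  if ("clade" %in% names(occurrences)) {
    clades <- dplyr::distinct(occurrences, .data$species, .data$clade)
    records <- dplyr::left_join(records, clades, by = "species")
  }

  # assemblage summaries + predictors
  assemblages <- summarize_assemblage(records, occ_a, tb)
  ab <- occ_a |>
    dplyr::filter(.data$time_bin %in% tb$bins) |>
    dplyr::distinct(.data$region_id, .data$time_bin, .data$species) |>
    dplyr::inner_join(dplyr::select(niches, "species", "sti"),
                      by = "species") |>
    dplyr::inner_join(climate$medians, by = c("region_id", "time_bin")) |>
    dplyr::group_by(.data$region_id, .data$time_bin) |>
    dplyr::summarise(
      res = assemblage_bias(.data$sti, .data$median_t[1]),
      .groups = "drop") |>
    tidyr::unpack("res")
  assemblages <- assemblages |>
    dplyr::left_join(
      dplyr::select(ab, "region_id", "time_bin",
                    assemblage_bias = "bias", "bias_sd", cti_i = "cti"),
      by = c("region_id", "bin_i" = "time_bin")) |>
    dplyr::left_join(
      dplyr::select(ab, "region_id", "time_bin", bias_i1 = "bias"),
      by = c("region_id", "bin_i1" = "time_bin")) |>
    dplyr::mutate(bias_change = .data$bias_i1 - .data$assemblage_bias) |>
    dplyr::left_join(
      dplyr::select(climate$deltas, "region_id", "boundary", "delta_t",
                    "phase", "warming_associated"),
      by = c("region_id", "boundary"))
  hab <- habitat_change(occ_a, tb)
  if (!is.null(hab)) {
    assemblages <- dplyr::left_join(assemblages, hab,
                                    by = c("region_id", "boundary"))
  }

  # inference
  species_dat <- if (config$warming_only &&
                     "warming_associated" %in% names(records)) {
    dplyr::filter(records, .data$warming_associated)
  } else {
    records
  }
  species_fit <- if (nrow(species_dat) >= 10 &&
                     length(unique(species_dat$level_pooled)) >= 2) {
    fit_species_model(species_dat, fixed = config$species_fixed)
  } else {
    NULL
  }
  slopes <- per_context_slopes(records, climate$deltas,
                               pooling = config$pooling)
  slope_fit <- tryCatch(
    slope_vs_warming(slopes, min_species = config$min_species),
    error = function(e) NULL)
  assemblage_fits <- tryCatch(
    fit_assemblage_models(assemblages),
    error = function(e) NULL)
  predictions <- if (!is.null(assemblage_fits) &&
                     nrow(assemblage_fits) > 0) {
    tryCatch(predict_at_warming(assemblage_fits,
                                delta_t = config$prediction_delta_t),
             error = function(e) NULL)
  } else {
    NULL
  }

  report <- list(
    n_input = n_input,
    n_analysed_bins = sum(occurrences$time_bin %in% tb$bins),
    n_flanking = sum(occurrences$time_bin %in% tb$flanking),
    n_no_temperature = n_no_temp,
    n_in_analyzable_regions = nrow(occ_a),
    n_regions = nrow(asg$regions),
    n_regions_analyzable = length(analyzable),
    n_response_records = nrow(records),
    n_unclassified = n_unclassified,
    n_dropped_no_bias = n_no_bias,
    n_assemblages = nrow(assemblages)
  )
  list(occurrences = occ, regions = asg$regions, niches = niches,
       climate = climate, records = records, assemblages = assemblages,
       species_fit = species_fit, slopes = slopes, slope_fit = slope_fit,
       assemblage_fits = assemblage_fits, predictions = predictions,
       report = report, config = config)
}

habitat_change <- function(occ, tb) {
  if (!all(c("lith_category", "bath_category") %in% names(occ))) {
    return(NULL)
  }
  props <- occ |>
    dplyr::filter(.data$time_bin %in% tb$bins) |>
    dplyr::group_by(.data$region_id, .data$time_bin) |>
    dplyr::summarise(
      pct_carbonate = 100 * mean(.data$lith_category == "carbonate"),
      pct_deep = 100 * mean(.data$bath_category == "deep"),
      .groups = "drop")
  bb <- bin_boundaries(tb)
  tidyr::crossing(region_id = unique(props$region_id), bb) |>
    dplyr::left_join(dplyr::rename(props, pc_i = "pct_carbonate",
                                   pd_i = "pct_deep"),
                     by = c("region_id", "bin_i" = "time_bin")) |>
    dplyr::left_join(dplyr::rename(props, pc_i1 = "pct_carbonate",
                                   pd_i1 = "pct_deep"),
                     by = c("region_id", "bin_i1" = "time_bin")) |>
    dplyr::transmute(.data$region_id, .data$boundary,
                     d_pct_carbonate = .data$pc_i1 - .data$pc_i,
                     d_pct_deep = .data$pd_i1 - .data$pd_i)
}

#' Sensitivity matrix over pipeline configuration axes
#'
#' Re-runs the pipeline over the cross-product of the supplied
#' configuration axes (e.g. classification scheme x pooling rule) and
#' collates the species-level thermal-bias coefficient per cell.
#'
#' @param occurrences,fields,range_table,tb As [run_pipeline()].
#' @param config Base [pipeline_config()] whose entries the axes
#'   override.
#' @param axes Named list of value vectors, names matching
#'   [pipeline_config()] arguments (e.g.
#'   `list(scheme = c("two_timer", "three_timer"))`). Empty list -> a
#'   single run.
#' @return Tibble with one row per cell: the axis values, `estimate`,
#'   `std_error`, `p_value`, `n_obs` of the thermal-bias coefficient.
#' @export
sensitivity_matrix <- function(occurrences, fields, range_table = NULL,
                               tb = time_bins(),
                               config = pipeline_config(),
                               axes = list()) {
  cells <- if (length(axes) == 0) {
    list(list())
  } else {
    grid <- do.call(tidyr::crossing, axes)
    purrr::pmap(grid, list)
  }
  purrr::map_dfr(cells, function(cell) {
    cfg <- config
    for (nm in names(cell)) cfg[[nm]] <- cell[[nm]]
    out <- run_pipeline(occurrences, fields, range_table, tb, cfg)
    co <- if (!is.null(out$species_fit)) {
      dplyr::filter(out$species_fit$coefficients,
                    .data$term == "thermal_bias")
    } else {
      tibble::tibble(estimate = NA_real_, std_error = NA_real_,
                     p_value = NA_real_)
    }
    dplyr::bind_cols(
      if (length(cell) > 0) tibble::as_tibble(cell) else NULL,
      tibble::tibble(estimate = co$estimate, std_error = co$std_error,
                     p_value = co$p_value,
                     n_obs = if (!is.null(out$species_fit)) {
                       out$species_fit$n_obs
                     } else {
                       NA_integer_
                     }))
  })
}
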