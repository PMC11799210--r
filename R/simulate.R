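#' Configuration for the synthetic occurrence world
#'
#' Defines a simulated study system with known ground truth: species with
#' conserved Gaussian thermal niches (optimum + breadth), regions arranged
#' along a latitudinal temperature gradient, a shared temperature
#' trajectory over the ordered time bins spanning stasis, two warming
#' pulses, a transitional step and renewed stasis, detection probability
#' per region-bin, and an optional anoxia mask that silences region-bins
#' regardless of thermal suitability.
#'
#' Defaults emulate the empirical setting: mid-latitude epicontinental
#' seas with regional summer means of roughly 17-27 degrees C in the cool
#' interval, per-boundary warming steps near +4.5 degrees C through the
#' two warming pulses (about +9 degrees C combined), species optima spread
#' over the sampled 14-34 degrees C window, a clade mix dominated by
#' bivalve- and brachiopod-like species with the brachiopod analogue given
#' the narrower niche breadth, and imperfect (0.7) detection.
#'
#' @param n_species Number of species; default 500.
#' @param clades Named numeric vector of clade mixing proportions.
#' @param breadths Named numeric vector of per-clade niche breadth (SD of
#'   the Gaussian suitability kernel, degrees C).
#' @param optimum_range Range (degrees C) of the uniform distribution of
#'   species optima.
#' @param n_regions Number of regions; default 5.
#' @param region_lats,region_lons Region center coordinates (recycled to
#'   `n_regions`).
#' @param spatial_spread SD (degrees) of locality jitter around region
#'   centers.
#' @param tb A [time_bins()] object.
#' @param trajectory Named numeric vector of temperature offsets (degrees
#'   C) per bin label, flanking bins included, added to each region's
#'   baseline.
#' @param lat_gradient Degrees C of cooling per degree latitude in the
#'   baseline field.
#' @param base_intercept Baseline SST at latitude 0, degrees C.
#' @param p_max Maximum per-bin presence probability at the thermal
#'   optimum.
#' @param detection Detection probability per region-bin (scalar, or a
#'   matrix regions x bins incl. flanking).
#' @param occ_rate Poisson rate for extra occurrence rows per detected
#'   presence (each presence emits `1 + rpois(occ_rate)` occurrences).
#' @param anoxia Tibble with columns `region_id`, `time_bin` naming
#'   region-bins whose detection is forced to zero, or `NULL`.
#' @param suitability "gaussian" (default) or "flat" (presence probability
#'   `p_max / 2` everywhere — responses independent of temperature, the
#'   null world).
#' @param seed Integer seed; every random draw in [generate_world()]
#'   descends from it.
#' @return A `world_config` list.
#' @export
world_config <- function(n_species = 500L,
                         clades = c(Bivalvia = 0.55,
                                    Rhynchonelliformea = 0.35,
                                    Gastropoda = 0.10),
                         breadths = c(Bivalvia = 5,
                                      Rhynchonelliformea = 3,
                                      Gastropoda = 5),
                         optimum_range = c(14, 34),
                         n_regions = 5L,
                         region_lats = c(26, 32, 38, 44, 50),
                         region_lons = c(0, 8, 4, 12, 6),
                         spatial_spread = 1.5,
                         tb = time_bins(),
                         trajectory = NULL,
                         lat_gradient = 0.35,
                         base_intercept = 36,
                         p_max = 0.9,
                         detection = 0.7,
                         occ_rate = 0.6,
                         anoxia = NULL,
                         suitability = c("gaussian", "flat"),
                         seed = 1L) {
  suitability <- match.arg(suitability)
  all_bins <- c(tb$flanking[1], tb$bins, tb$flanking[2])
  if (is.null(trajectory)) {
    # stasis, stasis, +4.5, +4.5, +1 (peak), -0.3: two warming pulses then
    # a warm plateau; flanks continue the adjacent state
    offs <- c(0, 0, 0.2, 4.7, 9.2, 10.2, 9.9, 9.9)
    if (length(all_bins) != length(offs)) {
      offs <- rep(0, length(all_bins))
    }
    trajectory <- setNames(offs, all_bins)
  }
  stopifnot(all(all_bins %in% names(trajectory)))
  region_lats <- rep_len(region_lats, n_regions)
  region_lons <- rep_len(region_lons, n_regions)
  if (is.matrix(detection)) {
    stopifnot(nrow(detection) == n_regions,
              ncol(detection) == length(all_bins))
  } else {
    detection <- matrix(detection, n_regions, length(all_bins))
  }
  structure(list(
    n_species = as.integer(n_species), clades = clades,
    breadths = breadths, optimum_range = optimum_range,
    n_regions = as.integer(n_regions), region_lats = region_lats,
    region_lons = region_lons, spatial_spread = spatial_spread,
    tb = tb, trajectory = trajectory[all_bins],
    lat_gradient = lat_gradient, base_intercept = base_intercept,
    p_max = p_max, detection = detection, occ_rate = occ_rate,
    anoxia = anoxia, suitability = suitability, seed = as.integer(seed)
  ), class = "world_config")
}

#' Generate a synthetic occurrence world
#'
#' Realizes a [world_config()]: regional ambient temperatures follow the
#' latitudinal baseline plus the per-bin trajectory; each species is
#' present in a region-bin with probability given by its Gaussian thermal
#' suitability at the regional ambient; detected presences emit occurrence
#' rows at jittered localities; temperature fields per analysed bin are
#' smooth latitudinal gradients consistent with the regional ambients; the
#' range table is computed from the realized (pre-detection) global
#' presence, mimicking a well-sampled global reference dataset. Fully
#' reproducible given the seed: random number streams are split per
#' component (niches, presence, detection, localities) so toggling one
#' does not perturb the others.
#'
#' @param config A [world_config()].
#' @return A list: `occurrences` (tibble ready for the pipeline, flanking
#'   bins included), `fields` (named list of [temperature_field()] per
#'   analysed bin), `range_table` (as [compute_range_table()]),
#'   `ground_truth` (list: `species`, `region_bins`, `presence`), and
#'   `config`.
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  tb <- config$tb
  all_bins <- names(config$trajectory)
  nb <- length(all_bins)
  nr <- config$n_regions
  ns <- config$n_species

  # -- species niches --------------------------------------------------
  set.seed(config$seed)
  clade <- sample(names(config$clades), ns, replace = TRUE,
                  prob = config$clades)
  optimum <- runif(ns, config$optimum_range[1], config$optimum_range[2])
  breadth <- unname(config$breadths[clade])
  species <- sprintf("sp%04d", seq_len(ns))
  truth_species <- tibble::tibble(species = species, clade = clade,
                                  optimum = optimum, breadth = breadth)

  # -- regional ambients and detection --------------------------------
  base_t <- config$base_intercept - config$lat_gradient * config$region_lats
  ambient <- outer(base_t, unname(config$trajectory), `+`)   # nr x nb
  detection <- config$detection
  anoxia <- matrix(FALSE, nr, nb, dimnames = list(NULL, all_bins))
  if (!is.null(config$anoxia)) {
    for (r in seq_len(nrow(config$anoxia))) {
      anoxia[config$anoxia$region_id[r],
             config$anoxia$time_bin[r]] <- TRUE
    }
    detection[anoxia] <- 0
  }
  truth_rb <- tibble::tibble(
    region_id = rep(seq_len(nr), nb),
    time_bin = rep(all_bins, each = nr),
    ambient_t = as.vector(ambient),
    detection = as.vector(detection),
    anoxia = as.vector(anoxia)
  )

  # -- realized presence ----------------------------------------------
  set.seed(config$seed + 1000003L)
  suit <- function(t, opt, sigma) {
    if (config$suitability == "flat") {
      rep(config$p_max / 2, length(opt))
    } else {
      config$p_max * exp(-(t - opt)^2 / (2 * sigma^2))
    }
  }
  pres <- array(FALSE, c(ns, nr, nb))
  for (r in seq_len(nr)) {
    for (b in seq_len(nb)) {
      p <- suit(ambient[r, b], optimum, breadth)
      pres[, r, b] <- runif(ns) < p
    }
  }

  # -- detection ------------------------------------------------------
  set.seed(config$seed + 2000003L)
  det <- array(FALSE, c(ns, nr, nb))
  for (r in seq_len(nr)) {
    for (b in seq_len(nb)) {
      if (detection[r, b] <= 0) next
      det[, r, b] <- pres[, r, b] & (runif(ns) < detection[r, b])
    }
  }

  # -- occurrence rows -------------------------------------------------
  set.seed(config$seed + 3000003L)
  idx <- which(det, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    n_occ <- 1L + rpois(nrow(idx), config$occ_rate)
    rows <- rep(seq_len(nrow(idx)), n_occ)
    total <- length(rows)
    occ <- tibble::tibble(
      occurrence_id = sprintf("occ%06d", seq_len(total)),
      species = species[idx[rows, 1]],
      clade = clade[idx[rows, 1]],
      region_id_true = as.integer(idx[rows, 2]),
      time_bin = all_bins[idx[rows, 3]],
      paleo_lon_primary = config$region_lons[idx[rows, 2]] +
        rnorm(total, 0, config$spatial_spread),
      paleo_lat_primary = config$region_lats[idx[rows, 2]] +
        rnorm(total, 0, config$spatial_spread)
    )
    occ$paleo_lon_secondary <- occ$paleo_lon_primary - 2
    occ$paleo_lat_secondary <- occ$paleo_lat_primary - 1
    occ$modern_lon <- occ$paleo_lon_primary
    occ$modern_lat <- occ$paleo_lat_primary
  } else {
    warning("degenerate configuration: no occurrences emitted")
    occ <- tibble::tibble(
      occurrence_id = character(), species = character(),
      clade = character(), region_id_true = integer(),
      time_bin = character(), paleo_lon_primary = numeric(),
      paleo_lat_primary = numeric(), paleo_lon_secondary = numeric(),
      paleo_lat_secondary = numeric(), modern_lon = numeric(),
      modern_lat = numeric())
  }

  # -- temperature fields (analysed bins) ------------------------------
  lon_axis <- seq(min(config$region_lons) - 8,
                  max(config$region_lons) + 8, by = 1)
  lat_axis <- seq(min(config$region_lats) - 8,
                  max(config$region_lats) + 8, by = 1)
  fields <- lapply(tb$bins, function(b) {
    vals <- outer(rep(1, length(lon_axis)),
                  config$base_intercept - config$lat_gradient * lat_axis +
                    config$trajectory[[b]])
    temperature_field(lon_axis, lat_axis, vals,
                      geography_tag = "synthetic", scenario_tag = b)
  })
  names(fields) <- tb$bins

  # -- range table from realized (pre-detection) global presence -------
  glob <- which(apply(pres, c(1, 3), any), arr.ind = TRUE)
  range_table <- compute_range_table(
    tibble::tibble(species = species[glob[, 1]],
                   time_bin = all_bins[glob[, 2]]), tb)

  pidx <- which(pres, arr.ind = TRUE)
  presence_long <- tibble::tibble(
    species = species[pidx[, 1]],
    region_id = as.integer(pidx[, 2]),
    time_bin = all_bins[pidx[, 3]]
  )

  list(occurrences = occ, fields = fields, range_table = range_table,
       ground_truth = list(species = truth_species,
                           region_bins = truth_rb,
                           presence = presence_long),
       config = config)
}

#' Named scenario presets for the synthetic world
#'
#' * `tracking`: species occupy regions by Gaussian thermal suitability
#'   through the warming trajectory — the bias-response gradient should
#'   emerge (negative bias coefficient at the species level).
#' * `null`: presence probability independent of temperature AND a
#'   stationary temperature trajectory — no climate signal of any kind, so
#'   the bias coefficient should be indistinguishable from zero. (A world
#'   that warms is not a clean null even with temperature-blind occupancy:
#'   the per-level context-bin convention offsets immigrant and leaver
#'   biases by the warming step, a measurement artifact discussed in the
#'   vignette.)
#' * `anoxia`: as `tracking`, but the two northern (coolest) regions are
#'   anoxia-masked through the second warming pulse and the transitional
#'   bin, severing the bias-response link there.
#' * `clade_contrast`: as `tracking`, with a markedly narrower niche
#'   breadth for the brachiopod analogue than the bivalve analogue.
#'
#' @param seed Integer seed stored in each config.
#' @param n_species Species count per config; default 500.
#' @return Named list of [world_config()] objects.
#' @export
scenario_presets <- function(seed = 1L, n_species = 500L) {
  tb <- time_bins()
  list(
    tracking = world_config(n_species = n_species, seed = seed),
    null = {
      all_bins <- c(tb$flanking[1], tb$bins, tb$flanking[2])
      world_config(n_species = n_species, suitability = "flat",
                   trajectory = setNames(rep(0, length(all_bins)),
                                         all_bins),
                   seed = seed)
    },
    anoxia = world_config(
      n_species = n_species, seed = seed,
      anoxia = tidyr::crossing(region_id = 4:5,
                               time_bin = c("Exaratum", "Falciferum"))),
    clade_contrast = world_config(
      n_species = n_species, seed = seed,
      breadths = c(Bivalvia = 6, Rhynchonelliformea = 2.5,
                   Gastropoda = 6))
  )
}

#' Evaluate a scenario preset through the analysis chain
#'
#' Generates a preset world and runs the species-level analysis on it:
#' temperatures sampled at occurrence coordinates from the generated
#' fields, STIs pooled across the analysed bins, two-timer classification
#' against the generated range table, thermal bias in the per-level
#' context bin, merged pooling, and the nested mixed-effects regression of
#' response level on thermal bias. Regions are taken from the generator's
#' ground truth so the evaluation isolates the classification and
#' inference stages (the clustering stage is exercised by
#' [run_pipeline()]).
#'
#' @param preset Name of a [scenario_presets()] entry.
#' @param seed Seed forwarded to the preset.
#' @param n_species Species count; default 500.
#' @param subset Which records enter the model: "warming"
#'   (warming-associated boundaries; default), "all", or "masked"
#'   (boundaries touching an anoxia-masked region-bin — only meaningful
#'   for the anoxia preset).
#' @param fixed Fixed-effect terms for [fit_species_model()].
#' @return A list: `fit` (the `species_response_fit`, or `NULL` if the
#'   subset is degenerate), `coefficients` (its fixed-effect table),
#'   `records` (the classified, bias-attached records of the subset), and
#'   `level_means` (mean thermal bias per pooled level, computed with all
#'   levels contextualized at time i — a common ambient is required for
#'   level means to compare species preferences rather than the warming
#'   step between the context bins).
#' @export
evaluate_preset <- function(preset, seed, n_species = 500L,
                            subset = c("warming", "all", "masked"),
                            fixed = "thermal_bias") {
  subset <- match.arg(subset)
  cfg <- scenario_presets(seed = seed, n_species = n_species)[[preset]]
  if (is.null(cfg)) stop("unknown preset: ", preset, call. = FALSE)
  w <- generate_world(cfg)
  tb <- cfg$tb
  occ <- w$occurrences
  occ$region_id <- occ$region_id_true
  occ$temperature <- NA_real_
  for (b in tb$bins) {
    sel <- which(occ$time_bin == b)
    occ$temperature[sel] <- sample_temperature(
      w$fields[[b]], occ$paleo_lon_primary[sel],
      occ$paleo_lat_primary[sel])
  }
  niches <- species_sti(dplyr::filter(occ, .data$time_bin %in% tb$bins))
  climate <- regional_climate(occ, tb)
  rec0 <- classify_occupancy(occ, w$range_table, tb)
  rec_common <- attach_bias(rec0, niches, climate$medians,
                            context = "bin_i")
  rec <- attach_bias(rec0, niches, climate$medians)
  rec <- dplyr::left_join(
    rec,
    dplyr::select(climate$deltas, "region_id", "boundary", "delta_t",
                  "warming_associated"),
    by = c("region_id", "boundary"))
  rec <- pool_levels(rec)
  if (any(grepl("clade", fixed))) {
    rec <- dplyr::left_join(
      rec, dplyr::distinct(w$occurrences, .data$species, .data$clade),
      by = "species")
  }
  dat <- switch(
    subset,
    all = rec,
    warming = dplyr::filter(rec, .data$warming_associated),
    masked = {
      anox <- dplyr::filter(w$ground_truth$region_bins, .data$anoxia)
      bb <- bin_boundaries(tb)
      masked_b <- dplyr::bind_rows(
        dplyr::inner_join(anox, bb, by = c("time_bin" = "bin_i")),
        dplyr::inner_join(anox, bb, by = c("time_bin" = "bin_i1")))
      dplyr::semi_join(rec, masked_b, by = c("region_id", "boundary"))
    })
  fit <- if (nrow(dat) >= 10 &&
             length(unique(dat$level_pooled)) >= 2) {
    fit_species_model(dat, fixed = fixed)
  } else {
    NULL
  }
  level_means <- rec_common |>
    dplyr::semi_join(dat, by = c("species", "region_id", "boundary")) |>
    pool_levels() |>
    dplyr::group_by(.data$level_pooled) |>
    dplyr::summarise(mean_bias = mean(.data$thermal_bias),
                     n = dplyr::n(), .groups = "drop")
  list(fit = fit,
       coefficients = if (!is.null(fit)) fit$coefficients else NULL,
       records = dat, level_means = level_means)
}
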