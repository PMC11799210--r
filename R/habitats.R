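#' Habitat category keys
#'
#' Exact membership lists used to collapse the diverse depositional
#' lithology and depositional environment vocabularies of Paleobiology
#' Database downloads into two-state habitat axes: substrate (carbonate vs
#' siliciclastic) and bathymetry (shallow vs deep). Strings not in any list
#' map to "unknown".
#'
#' @return A named list with character vectors `carbonate`, `siliciclastic`,
#'   `shallow`, `deep`.
#' @examples
#' habitat_keys()$carbonate
#' @export
habitat_keys <- function() {
  list(
    carbonate = c(
      "carbonate", "limestone", "reef rocks", "bafflestone", "bindstone",
      "dolomite", "framestone", "grainstone", "lime mudstone", "packstone",
      "rudstone", "floatstone", "wackestone"
    ),
    siliciclastic = c(
      "shale", "siliciclastic", "volcaniclastic", "claystone",
      "conglomerate", "mudstone", "phyllite", "quartzite", "sandstone",
      "siltstone", "slate", "schist"
    ),
    shallow = c(
      "coastal indet.", "delta front", "delta plain", "deltaic indet.",
      "estuary/bay", "foreshore", "interdistributary bay", "lagoonal",
      "lagoonal/restricted shallow subtidal", "marginal marine indet.",
      "open shallow subtidal", "fluvial-deltaic indet.", "paralic indet.",
      "peritidal", "prodelta", "sand shoal", "shallow subtidal indet.",
      "shoreface", "transition zone/lower shoreface",
      "intrashelf/intraplatform reef", "reef, buildup or bioherm",
      "perireef or subreef", "platform/shelf-margin reef"
    ),
    deep = c(
      "basinal (carbonate)", "basinal (siliceous)", "basinal (siliciclastic)",
      "deep-water indet.", "deep subtidal indet.", "deep subtidal ramp",
      "deep subtidal shelf", "offshore", "offshore indet.", "offshore shelf",
      "slope", "submarine fan", "offshore ramp", "basin reef",
      "slope/ramp reef"
    )
  )
}

#' Categorize lithology and depositional environment into habitat classes
#'
#' Pure lookup against [habitat_keys()]: a lithology string belonging to the
#' carbonate (siliciclastic) list yields `lith_category` "carbonate"
#' ("siliciclastic"); an environment string in the shallow (deep) list
#' yields `bath_category` "shallow" ("deep"). Matching is exact after
#' trimming and lower-casing; anything else is "unknown". Vectorized.
#'
#' @param lithology Character vector of depositional lithology strings.
#' @param environment Character vector of depositional environment strings
#'   (recycled against `lithology` if length 1, and vice versa).
#' @return A tibble with columns `lith_category` and `bath_category`, each a
#'   factor-free character in `c("carbonate","siliciclastic","unknown")` and
#'   `c("shallow","deep","unknown")` respectively.
#' @examples
#' categorize_habitat("wackestone", "lagoonal")
#' categorize_habitat("sandstone", "offshore shelf")
#' categorize_habitat("tuff", "cave")
#' @export
categorize_habitat <- function(lithology, environment) {
  n <- max(length(lithology), length(environment))
  lithology <- rep_len(as.character(lithology), n)
  environment <- rep_len(as.character(environment), n)
  keys <- habitat_keys()
  norm <- function(x) stringr::str_squish(tolower(ifelse(is.na(x), "", x)))
  lith <- norm(lithology)
  env <- norm(environment)
  lith_category <- dplyr::case_when(
    lith %in% keys$carbonate ~ "carbonate",
    lith %in% keys$siliciclastic ~ "siliciclastic",
    TRUE ~ "unknown"
  )
  bath_category <- dplyr::case_when(
    env %in% keys$shallow ~ "shallow",
    env %in% keys$deep ~ "deep",
    TRUE ~ "unknown"
  )
  tibble::tibble(lith_category = lith_category,
                 bath_category = bath_category)
}

#' Test a species' affinity for a habitat category
#'
#' Exact one-tailed binomial test of whether a species' occurrences deviate
#' from the dataset-wide background proportion of a focal habitat category
#' (e.g. carbonate substrate). The tail is taken in the direction of the
#' observed deviation; an observation exactly at expectation is assigned no
#' affinity with p = 1. Affinity is assigned to the focal category when the
#' species over-represents it with p below `alpha`, to the complement
#' category when it under-represents it with p below `alpha`, and is "none"
#' otherwise.
#'
#' @param n_in Number of the species' classifiable occurrences in the focal
#'   category.
#' @param n_total Total classifiable occurrences of the species (focal +
#'   complement; "unknown" excluded upstream).
#' @param background_prop Dataset-wide proportion of classifiable
#'   occurrences in the focal category, strictly between 0 and 1.
#' @param alpha Significance level; default 0.1.
#' @param categories Length-2 character: labels for the focal and complement
#'   categories, used to name the assigned affinity.
#' @param two_tailed If `TRUE`, double the one-tailed probability (capped at
#'   1). Default `FALSE`, matching the one-tailed convention of standard
#'   fossil-affinity tests.
#' @return A one-row tibble: `affinity`, `p_value`, `n_in`, `n_total`,
#'   `background_prop`.
#' @examples
#' affinity_test(10, 10, 0.5)            # strong focal affinity
#' affinity_test(5, 10, 0.5)             # exactly at expectation: none
#' affinity_test(0, 10, 0.5)             # complement affinity
#' @export
affinity_test <- function(n_in, n_total, background_prop, alpha = 0.1,
                          categories = c("focal", "complement"),
                          two_tailed = FALSE) {
  stopifnot(length(n_in) == 1, length(n_total) == 1,
            n_in >= 0, n_in <= n_total,
            background_prop > 0, background_prop < 1)
  if (n_total == 0) {
    return(tibble::tibble(affinity = "none", p_value = 1,
                          n_in = 0L, n_total = 0L,
                          background_prop = background_prop))
  }
  expected <- n_total * background_prop
  if (n_in > expected) {
    p <- pbinom(n_in - 1, n_total, background_prop, lower.tail = FALSE)
    direction <- categories[1]
  } else if (n_in < expected) {
    p <- pbinom(n_in, n_total, background_prop)
    direction <- categories[2]
  } else {
    p <- 1
    direction <- "none"
  }
  if (two_tailed) p <- min(1, 2 * p)
  affinity <- if (direction != "none" && p < alpha) direction else "none"
  tibble::tibble(affinity = affinity, p_value = p,
                 n_in = as.integer(n_in), n_total = as.integer(n_total),
                 background_prop = background_prop)
}

#' Habitat affinities for every species in an occurrence table
#'
#' Runs [affinity_test()] per species on each habitat axis (substrate:
#' carbonate vs siliciclastic; bathymetry: shallow vs deep), with the
#' background proportion computed dataset-wide over classifiable
#' occurrences (the "unknown" category is excluded from both numerator and
#' denominator).
#'
#' @param occurrences Tibble with columns `species`, `lith_category`,
#'   `bath_category` (as produced by [read_occurrences()]).
#' @param alpha Significance level passed to [affinity_test()].
#' @return Tibble with one row per species x axis: `species`, `axis`,
#'   `affinity`, `p_value`, `n_in`, `n_total`, `background_prop`.
#' @export
species_affinities <- function(occurrences, alpha = 0.1) {
  stopifnot(all(c("species", "lith_category", "bath_category") %in%
                  names(occurrences)))
  one_axis <- function(col, focal, complement, axis) {
    dat <- dplyr::filter(occurrences, .data[[col]] %in% c(focal, complement))
    if (nrow(dat) == 0) return(tibble::tibble())
    bg <- mean(dat[[col]] == focal)
    if (bg <= 0 || bg >= 1) return(tibble::tibble())
    dat |>
      dplyr::group_by(.data$species) |>
      dplyr::summarise(n_in = sum(.data[[col]] == focal),
                       n_total = dplyr::n(), .groups = "drop") |>
      dplyr::rowwise() |>
      dplyr::mutate(res = list(affinity_test(
        .data$n_in, .data$n_total, bg, alpha = alpha,
        categories = c(focal, complement)))) |>
      dplyr::ungroup() |>
      dplyr::transmute(.data$species, axis = axis,
                       affinity = purrr::map_chr(.data$res, "affinity"),
                       p_value = purrr::map_dbl(.data$res, "p_value"),
                       n_in = .data$n_in, n_total = .data$n_total,
                       background_prop = bg)
  }
  dplyr::bind_rows(
    one_axis("lith_category", "carbonate", "siliciclastic", "substrate"),
    one_axis("bath_category", "shallow", "deep", "bathymetry")
  )
}
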