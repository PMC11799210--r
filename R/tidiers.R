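#' Tidy a species occupancy-response fit
#'
#' @param x A `species_response_fit`.
#' @param ... Unused.
#' @return Tibble of fixed-effect terms: `term`, `estimate`, `std_error`,
#'   `t_value`, `df`, `p_value`.
#' @export
tidy.species_response_fit <- function(x, ...) {
  x$coefficients
}

#' @rdname tidy.species_response_fit
#' @return For `glance()`: one-row tibble with `r2_marginal`,
#'   `r2_conditional`, `n_obs`, `random_structure`, `reduced_random`.
#' @export
glance.species_response_fit <- function(x, ...) {
  tibble::tibble(r2_marginal = x$r2_marginal,
                 r2_conditional = x$r2_conditional,
                 n_obs = x$n_obs,
                 random_structure = x$random_structure,
                 reduced_random = x$reduced_random)
}

#' Tidy a slope-vs-warming fit
#'
#' @param x A `slope_warming_fit`.
#' @param ... Unused.
#' @export
tidy.slope_warming_fit <- function(x, ...) {
  tibble::tibble(term = "delta_t", estimate = x$coefficient,
                 std_error = x$se, conf_low = x$conf_low,
                 conf_high = x$conf_high, p_value = x$p_value)
}

#' @rdname tidy.slope_warming_fit
#' @export
glance.slope_warming_fit <- function(x, ...) {
  tibble::tibble(r_weighted = x$r_weighted,
                 r_standardized = x$r_standardized,
                 n_contexts = x$n_contexts,
                 min_species = x$min_species)
}

#' Tidy assemblage-level fits
#'
#' @param x An `assemblage_fits` object.
#' @param ... Unused.
#' @return The coefficient table without the model list-columns.
#' @export
tidy.assemblage_fits <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), -dplyr::any_of(c("fixef", "vcov")))
}
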