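#' Species-level occupancy-response regression
#'
#' Fits the ordered occupancy response (treated as continuous) against
#' thermal bias and optional covariates with nested random intercepts:
#' species within regions within time zones,
#' `response ~ fixed + (1 | time_zone) + (1 | time_zone:region) +
#' (1 | time_zone:region:species)`, by REML (lme4). A singular fit is
#' refitted with successively reduced random structure (innermost term
#' dropped first) and flagged; if every mixed structure is singular the
#' fixed effects come from ordinary least squares.
#'
#' The coefficient table reports t statistics with, by default, a
#' residual-based degrees-of-freedom approximation (df = n - p);
#' `df_method = "satterthwaite"` uses lmerTest instead when installed.
#' Marginal R2 is the fixed-effect variance share
#' `var(X b) / (var(X b) + sum(random variances) + residual variance)`;
#' conditional R2 adds the random variances to the numerator.
#'
#' @param records Response records carrying the response column
#'   (`level_pooled` from [pool_levels()], or `level`), `thermal_bias`,
#'   and any covariates named in `fixed` (e.g. `delta_t`, `clade`), plus
#'   the grouping columns `species`, `region_id`, and `time_zone_col`.
#' @param fixed Character vector of fixed-effect terms; default
#'   `"thermal_bias"`. Interactions use `:` as usual.
#' @param response Name of the response column; defaults to
#'   `"level_pooled"` if present, else `"level"`.
#' @param time_zone_col Column defining the time-zone grouping; default
#'   `"boundary"`.
#' @param min_clade_n When `"clade"` appears in `fixed`, clades with fewer
#'   records than this are dropped (too few to represent a clade);
#'   default 20.
#' @param clade_reference Reference level for the clade factor; default
#'   "Bivalvia" (used when present).
#' @param df_method "residual" (default) or "satterthwaite".
#' @param random "nested" (default: the reduction ladder described above)
#'   or "none" (random variances forced to zero; the fit is ordinary
#'   least squares and the fixed effects equal the OLS closed form).
#' @return Object of class `species_response_fit`: list with `coefficients`
#'   (tibble: term, estimate, std_error, t_value, df, p_value),
#'   `r2_marginal`, `r2_conditional`, `varcor` (named random variances),
#'   `n_obs`, `n_dropped_clade`, `formula`, `random_structure`,
#'   `reduced_random` (logical), `model` (the fitted lme4/lm object).
#' @export
fit_species_model <- function(records,
                              fixed = "thermal_bias",
                              response = NULL,
                              time_zone_col = "boundary",
                              min_clade_n = 20L,
                              clade_reference = "Bivalvia",
                              df_method = c("residual", "satterthwaite"),
                              random = c("nested", "none")) {
  df_method <- match.arg(df_method)
  random <- match.arg(random)
  if (is.null(response)) {
    response <- if ("level_pooled" %in% names(records)) {
      "level_pooled"
    } else {
      "level"
    }
  }
  dat <- tibble::as_tibble(records)
  stopifnot(all(c(response, "species", "region_id", time_zone_col) %in%
                  names(dat)))
  if (length(unique(dat[[response]])) < 2) {
    stop("need at least 2 distinct response levels", call. = FALSE)
  }
  n_dropped_clade <- 0L
  uses_clade <- any(grepl("clade", fixed))
  if (uses_clade) {
    keep <- dat |>
      dplyr::count(.data$clade) |>
      dplyr::filter(.data$n >= min_clade_n) |>
      dplyr::pull(.data$clade)
    n_dropped_clade <- sum(!dat$clade %in% keep)
    dat <- dplyr::filter(dat, .data$clade %in% keep)
    lev <- unique(dat$clade)
    if (clade_reference %in% lev) {
      dat$clade <- factor(dat$clade,
                          levels = c(clade_reference,
                                     setdiff(sort(lev), clade_reference)))
    } else {
      dat$clade <- factor(dat$clade)
    }
  }
  dat$..tz <- as.character(dat[[time_zone_col]])
  dat$..rg <- paste(dat$..tz, dat$region_id, sep = ":")
  dat$..sp <- paste(dat$..rg, dat$species, sep = ":")

  fixed_rhs <- paste(fixed, collapse = " + ")
  rand_terms <- c("(1 | ..tz)", "(1 | ..rg)", "(1 | ..sp)")
  # a grouping whose groups are all singletons is confounded with the
  # residual; drop it up front rather than fitting an unidentifiable model
  if (!anyDuplicated(dat$..sp)) rand_terms <- rand_terms[1:2]
  if (random == "none") rand_terms <- character(0)
  fit <- NULL
  reduced <- FALSE
  for (ndrop in seq_len(length(rand_terms)) - 1L) {
    rt <- rand_terms[seq_len(length(rand_terms) - ndrop)]
    f <- stats::as.formula(
      paste(response, "~", fixed_rhs, "+", paste(rt, collapse = " + ")))
    ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                              check.nobs.vs.nlev = "ignore",
                              check.nobs.vs.nRE = "ignore")
    cand <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(f, data = dat, REML = TRUE, control = ctrl))),
      error = function(e) NULL)
    if (!is.null(cand) && !lme4::isSingular(cand, tol = 1e-4)) {
      fit <- cand
      reduced <- ndrop > 0
      break
    }
  }
  if (is.null(fit)) {
    # requested, or every random structure singular/inestimable: the
    # reduction ends at ordinary least squares (zero random variance)
    fit <- lm(stats::as.formula(paste(response, "~", fixed_rhs)),
              data = dat)
    reduced <- random != "none"
  }
  is_mixed <- inherits(fit, "merMod")

  beta <- if (is_mixed) lme4::fixef(fit) else coef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  tval <- beta / se
  n <- nrow(dat)
  p <- length(beta)
  if (df_method == "satterthwaite" && is_mixed &&
      requireNamespace("lmerTest", quietly = TRUE)) {
    ltfit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(stats::formula(fit), data = dat, REML = TRUE)))
    ct <- stats::coef(summary(ltfit))
    dfree <- ct[, "df"]
    pval <- ct[, "Pr(>|t|)"]
  } else {
    dfree <- rep(n - p, p)
    pval <- 2 * pt(abs(tval), df = dfree, lower.tail = FALSE)
  }

  if (is_mixed) {
    vc <- lme4::VarCorr(fit)
    rand_var <- vapply(vc, function(m) m[1, 1], numeric(1))
  } else {
    vc <- list()
    rand_var <- numeric(0)
  }
  sigma2 <- stats::sigma(fit)^2
  var_fixed <- var(as.vector(stats::model.matrix(fit) %*% beta))
  denom <- var_fixed + sum(rand_var) + sigma2
  structure(list(
    coefficients = tibble::tibble(
      term = names(beta), estimate = unname(beta), std_error = unname(se),
      t_value = unname(tval), df = unname(dfree), p_value = unname(pval)),
    r2_marginal = var_fixed / denom,
    r2_conditional = (var_fixed + sum(rand_var)) / denom,
    varcor = c(rand_var, residual = sigma2),
    n_obs = n,
    n_dropped_clade = n_dropped_clade,
    formula = paste(response, "~", fixed_rhs),
    random_structure = if (is_mixed) {
      paste(names(vc), collapse = " + ")
    } else {
      "none (OLS fallback)"
    },
    reduced_random = reduced,
    df_method = df_method,
    model = fit
  ), class = "species_response_fit")
}

#' @export
print.species_response_fit <- function(x, ...) {
  cat("Species occupancy-response model:", x$formula, "\n")
  cat("random intercepts:", x$random_structure,
      if (x$reduced_random) "(reduced)" else "", "\n")
  print(as.data.frame(x$coefficients), digits = 3)
  cat(sprintf("n = %d; R2 marginal = %.3f; conditional = %.3f\n",
              x$n_obs, x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' Per-context regression slopes of thermal bias on response level
#'
#' For each (region, boundary) context with at least two distinct pooled
#' response levels, regresses species thermal bias on the ordered level
#' (after [pool_levels()], default 2/3/4) and keeps the slope — the mean
#' difference in thermal bias per response level — with its standard
#' error, the species count, and the regional warming magnitude.
#'
#' @param records Response records with `thermal_bias` (see
#'   [attach_bias()]); pooled internally via `pooling`.
#' @param climate_deltas Tibble `region_id`, `boundary`, `delta_t` (e.g.
#'   `regional_climate()$deltas`).
#' @param pooling Passed to [pool_levels()]; default "merged".
#' @return Tibble: `region_id`, `boundary`, `slope`, `se`, `n_species`,
#'   `n_levels`, `delta_t`.
#' @export
per_context_slopes <- function(records, climate_deltas,
                               pooling = "merged") {
  dat <- pool_levels(records, pooling)
  dat |>
    dplyr::group_by(.data$region_id, .data$boundary) |>
    dplyr::group_modify(function(d, key) {
      if (length(unique(d$level_pooled)) < 2) return(tibble::tibble())
      m <- lm(thermal_bias ~ level_pooled, data = d)
      sm <- summary(m)$coefficients
      tibble::tibble(slope = sm["level_pooled", "Estimate"],
                     se = sm["level_pooled", "Std. Error"],
                     n_species = nrow(d),
                     n_levels = length(unique(d$level_pooled)))
    }) |>
    dplyr::ungroup() |>
    dplyr::left_join(
      dplyr::select(climate_deltas, "region_id", "boundary", "delta_t"),
      by = c("region_id", "boundary"))
}

#' Inverse-variance-weighted regression of context slopes on warming
#'
#' Weighted least squares of the per-context bias-vs-level slopes on the
#' regional warming magnitude, with weights 1/SE^2, restricted to contexts
#' with at least `min_species` species. Reports the unstandardized
#' coefficient with its CI and two-tailed p, plus two correlation-scale
#' effects: the weighted Pearson correlation and the sign-carried
#' standardized slope (both labelled; they coincide for simple
#' regression).
#'
#' @param slopes Output of [per_context_slopes()].
#' @param min_species Minimum species per retained context; default 20.
#' @param conf_level Confidence level; default 0.95.
#' @return Object of class `slope_warming_fit`: list with `coefficient`,
#'   `se`, `conf_low`, `conf_high`, `p_value`, `r_weighted`,
#'   `r_standardized`, `n_contexts`, `min_species`, `model`.
#' @export
slope_vs_warming <- function(slopes, min_species = 20L,
                             conf_level = 0.95) {
  dat <- slopes |>
    dplyr::filter(.data$n_species >= min_species,
                  is.finite(.data$delta_t), is.finite(.data$se),
                  .data$se > 0)
  if (nrow(dat) < 3) {
    stop("need at least 3 contexts after filtering (have ", nrow(dat),
         ")", call. = FALSE)
  }
  w <- 1 / dat$se^2
  m <- lm(slope ~ delta_t, data = dat, weights = w)
  sm <- summary(m)$coefficients
  est <- sm["delta_t", "Estimate"]
  se <- sm["delta_t", "Std. Error"]
  dfree <- m$df.residual
  tcrit <- qt(1 - (1 - conf_level) / 2, dfree)
  wm <- function(x) sum(w * x) / sum(w)
  wsd <- function(x) sqrt(sum(w * (x - wm(x))^2) / sum(w))
  r_w <- sum(w * (dat$delta_t - wm(dat$delta_t)) *
               (dat$slope - wm(dat$slope))) /
    (sum(w) * wsd(dat$delta_t) * wsd(dat$slope))
  structure(list(
    coefficient = est, se = se,
    conf_low = est - tcrit * se, conf_high = est + tcrit * se,
    p_value = sm["delta_t", "Pr(>|t|)"],
    r_weighted = r_w,
    r_standardized = est * wsd(dat$delta_t) / wsd(dat$slope),
    n_contexts = nrow(dat), min_species = min_species,
    data = dat, model = m
  ), class = "slope_warming_fit")
}

#' @export
print.slope_warming_fit <- function(x, ...) {
  cat(sprintf(
    "Slope-vs-warming WLS: coef = %.3f [%.3f, %.3f], p = %.3g\n",
    x$coefficient, x$conf_low, x$conf_high, x$p_value))
  cat(sprintf("R (weighted) = %.3f; R (standardized slope) = %.3f; n = %d contexts (>= %d species)\n",
              x$r_weighted, x$r_standardized, x$n_contexts, x$min_species))
  invisible(x)
}

fit_nested_lm <- function(dat, response, predictor, weights = NULL,
                          time_zone_col = "boundary") {
  dat$..tz <- as.character(dat[[time_zone_col]])
  dat$..rg <- paste(dat$..tz, dat$region_id, sep = ":")
  dat$..w <- if (is.null(weights)) rep(1, nrow(dat)) else weights
  f_mixed <- stats::as.formula(
    paste(response, "~", predictor, "+ (1 | ..tz) + (1 | ..rg)"))
  method <- "lmm"
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(f_mixed, data = dat, weights = dat$..w, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular =
                                               "ignore")))),
    error = function(e) NULL)
  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-4)) {
    f_lm <- stats::as.formula(paste(response, "~", predictor))
    fit <- lm(f_lm, data = dat, weights = dat$..w)
    method <- "ols"
  }
  list(fit = fit, method = method)
}

#' Assemblage-level response regressions
#'
#' Fits each (response, predictor) pair on the assemblage summary table
#' with regions nested in time zones as random intercepts (falling back
#' to ordinary least squares, flagged, when the random structure is
#' singular or inestimable at small n). Models whose predictor is the
#' assemblage thermal bias are weighted by the inverse of the member-bias
#' standard deviation when `weight_bias_sd = TRUE` and a `bias_sd` column
#' is present. Coefficients are unstandardized: %-change (or turnover
#' change) per unit predictor.
#'
#' @param summaries Tibble with one row per (region, boundary) assemblage,
#'   carrying the response and predictor columns plus `region_id`,
#'   `boundary`, and optionally `bias_sd`.
#' @param responses Character vector of response column names; defaults to
#'   the assemblage-change percentages and turnover present in
#'   `summaries`.
#' @param predictors Character vector of predictor column names; defaults
#'   to `c("assemblage_bias", "delta_t")` intersected with `summaries`.
#' @param weight_bias_sd Weight assemblage-bias models by `1 / bias_sd`.
#' @param conf_level Confidence level for Wald intervals; default 0.95.
#' @param min_rows Minimum assemblage rows required; default 6.
#' @return Object of class `assemblage_fits`: tibble with one row per
#'   fitted pair (`response`, `predictor`, `estimate`, `std_error`,
#'   `conf_low`, `conf_high`, `p_value`, `n`, `method`) plus list-columns
#'   `fixef` and `vcov` used by [predict_at_warming()].
#' @export
fit_assemblage_models <- function(summaries,
                                  responses = NULL,
                                  predictors = NULL,
                                  weight_bias_sd = TRUE,
                                  conf_level = 0.95,
                                  min_rows = 6L) {
  default_resp <- c("pct_originating", "pct_immigrating",
                    "pct_extirpated", "pct_extinct", "jaccard_turnover",
                    "bias_change")
  default_pred <- c("assemblage_bias", "delta_t", "d_pct_carbonate",
                    "d_pct_deep")
  responses <- responses %||% intersect(default_resp, names(summaries))
  predictors <- predictors %||% intersect(default_pred, names(summaries))
  stopifnot(length(responses) > 0, length(predictors) > 0)

  rows <- purrr::map_dfr(responses, function(rv) {
    purrr::map_dfr(predictors, function(pv) {
      dat <- summaries[is.finite(summaries[[rv]]) &
                         is.finite(summaries[[pv]]), , drop = FALSE]
      if (nrow(dat) < min_rows) return(tibble::tibble())
      w <- NULL
      if (weight_bias_sd && pv == "assemblage_bias" &&
          "bias_sd" %in% names(dat) && all(is.finite(dat$bias_sd)) &&
          all(dat$bias_sd > 0)) {
        w <- 1 / dat$bias_sd
      }
      res <- fit_nested_lm(dat, rv, pv, weights = w)
      beta <- if (res$method == "lmm") lme4::fixef(res$fit) else
        coef(res$fit)
      V <- as.matrix(vcov(res$fit))
      se <- sqrt(diag(V))
      z <- stats::qnorm(1 - (1 - conf_level) / 2)
      tv <- beta[pv] / se[pv]
      dfree <- nrow(dat) - length(beta)
      tibble::tibble(
        response = rv, predictor = pv,
        estimate = unname(beta[pv]), std_error = unname(se[pv]),
        conf_low = unname(beta[pv] - z * se[pv]),
        conf_high = unname(beta[pv] + z * se[pv]),
        p_value = unname(2 * pt(abs(tv), dfree, lower.tail = FALSE)),
        n = nrow(dat), method = res$method,
        fixef = list(beta), vcov = list(V))
    })
  })
  structure(rows, class = c("assemblage_fits", class(rows)))
}

#' Predict an assemblage response at a stated warming
#'
#' Point prediction `intercept + coefficient * delta_t` from a fitted
#' assemblage model with the warming-magnitude predictor, with a
#' confidence interval propagated from the fixed-effect covariance
#' (`var = v11 + delta_t^2 v22 + 2 delta_t v12`).
#'
#' @param fits An `assemblage_fits` object from [fit_assemblage_models()].
#' @param delta_t Warming magnitude in degrees C; default +3.
#' @param response Restrict to these response names (default: all fitted
#'   rows whose predictor is `delta_t`).
#' @param conf_level Confidence level; default 0.95.
#' @return Tibble: `response`, `delta_t`, `prediction`, `conf_low`,
#'   `conf_high`.
#' @export
predict_at_warming <- function(fits, delta_t = 3, response = NULL,
                               conf_level = 0.95) {
  rows <- dplyr::filter(tibble::as_tibble(fits),
                        .data$predictor == "delta_t")
  if (!is.null(response)) {
    rows <- dplyr::filter(rows, .data$response %in% .env$response)
  }
  if (nrow(rows) == 0) stop("no fitted delta_t models", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  purrr::pmap_dfr(rows, function(response, fixef, vcov, ...) {
    b <- fixef
    V <- vcov
    pred <- b[1] + b[2] * delta_t
    vr <- V[1, 1] + delta_t^2 * V[2, 2] + 2 * delta_t * V[1, 2]
    tibble::tibble(response = response, delta_t = delta_t,
                   prediction = unname(pred),
                   conf_low = unname(pred - z * sqrt(vr)),
                   conf_high = unname(pred + z * sqrt(vr)))
  })
}

#' Correlation between two standardized assemblage responses
#'
#' Fits a nested random-effects regression between two z-standardized
#' assemblage response columns and returns the coefficient — on the
#' standardized scale this is the correlation-type R the assemblage
#' analyses report — with its p-value.
#'
#' @param summaries Assemblage summary tibble.
#' @param var_x,var_y Column names.
#' @return One-row tibble: `var_x`, `var_y`, `r`, `p_value`, `n`,
#'   `method`.
#' @export
assemblage_correlation <- function(summaries, var_x, var_y) {
  dat <- summaries[is.finite(summaries[[var_x]]) &
                     is.finite(summaries[[var_y]]), , drop = FALSE]
  dat$..x <- as.numeric(scale(dat[[var_x]]))
  dat$..y <- as.numeric(scale(dat[[var_y]]))
  res <- fit_nested_lm(dat, "..y", "..x")
  beta <- if (res$method == "lmm") lme4::fixef(res$fit) else coef(res$fit)
  se <- sqrt(diag(as.matrix(vcov(res$fit))))
  tv <- beta["..x"] / se["..x"]
  dfree <- nrow(dat) - length(beta)
  tibble::tibble(var_x = var_x, var_y = var_y,
                 r = unname(beta["..x"]),
                 p_value = unname(2 * pt(abs(tv), dfree,
                                         lower.tail = FALSE)),
                 n = nrow(dat), method = res$method)
}
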