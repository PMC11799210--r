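make_species_records <- function(n = 200, b = -0.3, group_sd = 0,
                                 seed = 51) {
  set.seed(seed)
  boundaries <- paste0("b", 1:4)
  regions <- 1:3
  dat <- tibble::tibble(
    species = sample(sprintf("sp%03d", 1:80), n, replace = TRUE),
    region_id = sample(regions, n, replace = TRUE),
    boundary = sample(boundaries, n, replace = TRUE),
    thermal_bias = rnorm(n, 0, 3)
  )
  g_tz <- rnorm(length(boundaries), 0, group_sd)
  g_rg <- rnorm(length(boundaries) * length(regions), 0, group_sd)
  names(g_tz) <- boundaries
  names(g_rg) <- as.vector(outer(boundaries, regions, paste, sep = ":"))
  dat$level_pooled <- 3 + b * dat$thermal_bias +
    g_tz[dat$boundary] + g_rg[paste(dat$boundary, dat$region_id,
                                    sep = ":")] +
    rnorm(n, 0, 0.6)
  dat
}

test_that("mixed model reduces to OLS when random variances are forced to zero", {
  dat <- make_species_records(group_sd = 0)
  fit <- fit_species_model(dat, random = "none")
  ols <- lm(level_pooled ~ thermal_bias, data = dat)
  expect_equal(unname(fit$coefficients$estimate), unname(coef(ols)),
               tolerance = 1e-6)
  expect_equal(unname(fit$coefficients$std_error),
               unname(summary(ols)$coefficients[, "Std. Error"]),
               tolerance = 1e-6)
  expect_false(fit$reduced_random)
  expect_s3_class(fit, "species_response_fit")
  # the adaptive path stays close to OLS on group-free data
  auto <- fit_species_model(dat)
  expect_equal(unname(auto$coefficients$estimate), unname(coef(ols)),
               tolerance = 0.05)
})

test_that("mixed model recovers group structure and reports sane R2", {
  dat <- make_species_records(n = 600, group_sd = 0.8, seed = 52)
  fit <- fit_species_model(dat)
  expect_lte(fit$r2_marginal, fit$r2_conditional)
  expect_lte(fit$r2_conditional, 1)
  expect_gte(fit$r2_marginal, 0)
  co <- fit$coefficients
  expect_true(all(co$std_error > 0))
  bias_row <- co[co$term == "thermal_bias", ]
  expect_lt(abs(bias_row$estimate - (-0.3)), 0.1)
  # tidy/glance accessors agree with the stored tables
  expect_equal(tidy(fit), fit$coefficients)
  expect_equal(glance(fit)$r2_marginal, fit$r2_marginal)
})

test_that("marginal R2 is invariant to predictor centering", {
  dat <- make_species_records(n = 400, group_sd = 0.5, seed = 53)
  f1 <- fit_species_model(dat)
  dat2 <- dplyr::mutate(dat,
                        thermal_bias = thermal_bias -
                          mean(thermal_bias))
  f2 <- fit_species_model(dat2)
  expect_equal(f1$r2_marginal, f2$r2_marginal, tolerance = 1e-6)
})

test_that("model refuses single-level responses", {
  dat <- make_species_records()
  dat$level_pooled <- 3
  expect_error(fit_species_model(dat), "distinct response levels")
})

test_that("per-context slopes: exact line, exclusions, closed-form match", {
  rec <- tibble::tibble(
    species = sprintf("s%d", 1:9),
    region_id = 1L, boundary = "b1",
    level = c(2, 2, 2, 3, 3, 3, 4, 4, 4),
    thermal_bias = c(2, 2, 2, 0, 0, 0, -2, -2, -2))
  deltas <- tibble::tibble(region_id = 1L, boundary = "b1", delta_t = 5)
  sl <- suppressWarnings(
    per_context_slopes(rec, deltas, pooling = "five_level"))
  expect_equal(sl$slope, -2)
  expect_equal(sl$delta_t, 5)
  # single-level contexts are excluded
  rec1 <- dplyr::mutate(rec, level = 3)
  expect_equal(nrow(per_context_slopes(rec1, deltas,
                                       pooling = "five_level")), 0)
  # random fixture equals the closed-form simple-regression slope
  set.seed(54)
  recr <- tibble::tibble(species = sprintf("s%d", 1:40), region_id = 2L,
                         boundary = "b2",
                         level = sample(2:4, 40, replace = TRUE),
                         thermal_bias = rnorm(40))
  slr <- per_context_slopes(
    recr, tibble::tibble(region_id = 2L, boundary = "b2", delta_t = 1),
    pooling = "five_level")
  x <- recr$level; y <- recr$thermal_bias
  expect_equal(slr$slope, sum((x - mean(x)) * (y - mean(y))) /
                 sum((x - mean(x))^2), tolerance = 1e-12)
})

test_that("pooled 3-level slopes equal 5-level slopes when extremes are empty", {
  set.seed(55)
  rec <- tibble::tibble(species = sprintf("s%d", 1:30), region_id = 1L,
                        boundary = "b1",
                        level = sample(2:4, 30, replace = TRUE),
                        thermal_bias = rnorm(30))
  deltas <- tibble::tibble(region_id = 1L, boundary = "b1", delta_t = 2)
  expect_equal(per_context_slopes(rec, deltas, "merged")$slope,
               per_context_slopes(rec, deltas, "five_level")$slope)
})

test_that("weighted slope regression recovers exact lines and honours weights", {
  # exact line with equal SEs
  sl <- tibble::tibble(region_id = 1:5, boundary = "b",
                       slope = -0.1 - 0.05 * (1:5), se = 1,
                       n_species = 30, delta_t = 1:5)
  fit <- suppressWarnings(slope_vs_warming(sl, min_species = 20))
  expect_equal(fit$coefficient, -0.05, tolerance = 1e-12)
  expect_lt(fit$p_value, 1e-6)
  # weight expansion: 1/se^2 in {1, 4} equals unweighted fit on
  # row-expanded data
  set.seed(56)
  sl2 <- tibble::tibble(region_id = 1:8, boundary = "b",
                        slope = rnorm(8), se = rep(c(1, 0.5), 4),
                        n_species = 25, delta_t = rnorm(8))
  fit2 <- slope_vs_warming(sl2, min_species = 20)
  expanded <- sl2[rep(seq_len(8), times = (1 / sl2$se^2)), ]
  ols <- lm(slope ~ delta_t, data = expanded)
  expect_equal(fit2$coefficient, unname(coef(ols)["delta_t"]),
               tolerance = 1e-10)
  # the species-count filter applies
  sl3 <- dplyr::mutate(sl2, n_species = c(25, 25, 25, rep(5, 5)))
  fit3 <- slope_vs_warming(sl3, min_species = 20)
  expect_equal(fit3$n_contexts, 3)
  expect_error(slope_vs_warming(dplyr::mutate(sl2, n_species = 1)),
               "at least 3 contexts")
})

make_summaries <- function(n_regions = 5, n_bounds = 5, b = 2,
                           seed = 57, sd_noise = 3) {
  set.seed(seed)
  tidyr::crossing(region_id = seq_len(n_regions),
                  boundary = paste0("b", seq_len(n_bounds))) |>
    dplyr::mutate(delta_t = runif(dplyr::n(), -2, 10),
                  assemblage_bias = rnorm(dplyr::n(), -2, 2),
                  bias_sd = runif(dplyr::n(), 1, 3),
                  pct_immigrating = 10 + b * delta_t +
                    rnorm(dplyr::n(), 0, sd_noise))
}

test_that("assemblage models: constant response gives zero coefficient", {
  sm <- make_summaries()
  sm$pct_immigrating <- 25
  fits <- suppressWarnings(
    fit_assemblage_models(sm, responses = "pct_immigrating",
                          predictors = "delta_t"))
  expect_equal(fits$estimate, 0, tolerance = 1e-8)
})

test_that("assemblage models recover a known slope and weights are neutral when equal", {
  sm <- make_summaries(b = 2)
  fits <- fit_assemblage_models(sm, responses = "pct_immigrating",
                                predictors = "delta_t")
  expect_lt(abs(fits$estimate - 2), 1)
  expect_true(fits$conf_low < 2 & fits$conf_high > 2)
  # equal bias SDs: weighted and unweighted coefficients coincide
  sm$bias_sd <- 2
  w_on <- fit_assemblage_models(sm, responses = "pct_immigrating",
                                predictors = "assemblage_bias",
                                weight_bias_sd = TRUE)
  w_off <- fit_assemblage_models(sm, responses = "pct_immigrating",
                                 predictors = "assemblage_bias",
                                 weight_bias_sd = FALSE)
  expect_equal(w_on$estimate, w_off$estimate, tolerance = 1e-8)
})

test_that("warming predictions propagate the coefficient covariance", {
  sm <- make_summaries(b = 2, sd_noise = 1)
  fits <- fit_assemblage_models(sm, responses = "pct_immigrating",
                                predictors = "delta_t")
  # at delta_t = 0 the prediction is the intercept
  p0 <- predict_at_warming(fits, delta_t = 0)
  expect_equal(p0$prediction, unname(fits$fixef[[1]][1]))
  p3 <- predict_at_warming(fits, delta_t = 3)
  b <- fits$fixef[[1]]
  expect_equal(p3$prediction, unname(b[1] + 3 * b[2]))
  expect_lt(p3$conf_low, p3$prediction)
  expect_gt(p3$conf_high, p3$prediction)
  # zero-slope model predicts the intercept at any warming
  smc <- sm; smc$pct_immigrating <- 25
  fc <- suppressWarnings(
    fit_assemblage_models(smc, responses = "pct_immigrating",
                          predictors = "delta_t"))
  expect_equal(predict_at_warming(fc, delta_t = 7)$prediction, 25,
               tolerance = 1e-6)
})

test_that("standardized assemblage correlations are symmetric and bounded", {
  sm <- make_summaries(b = 2)
  sm$pct_extirpated <- 5 + 0.5 * sm$pct_immigrating +
    rnorm(nrow(sm), 0, 4)
  r1 <- assemblage_correlation(sm, "pct_immigrating", "pct_extirpated")
  r2 <- assemblage_correlation(sm, "pct_extirpated", "pct_immigrating")
  expect_equal(r1$r, r2$r, tolerance = 1e-6)
  expect_lte(abs(r1$r), 1)
})
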