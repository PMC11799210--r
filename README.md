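# thermalbias

Linking species' thermal preferences to their regional occupancy
dynamics across warming intervals, for fossil (and fossil-like)
occurrence data.

Marine ectotherm distributions track temperature. A species' long-term
thermal optimum — its **species temperature index**, STI, estimated here
as the median of ambient temperatures over all of its occurrences — can
be compared with the ambient temperature of a region at a time to give
its **thermal bias**,

```
bias = STI − T_ambient
```

(positive: the species prefers warmer water than it occupies). When a
region warms, theory predicts an ordered gradient of occupancy
responses along this bias: warm-preferring species immigrate (or, at
their dataset-wide first appearance, originate), intermediate species
persist, cold-preferring species are extirpated and — when no suitable
habitat remains — go extinct. Encoding the responses as an ordered level
(originating = 1 … extinct = 5), the core species-level model is the
nested mixed-effects regression

```
Occupancy_response ~ Thermal_bias  (+ ΔT_regional + clade + interactions)
random intercepts: species within region within time zone
```

with per-(region, boundary) bias-on-level slopes feeding an
inverse-variance-weighted meta-regression on regional warming magnitude,
and assemblage-level models relating the community temperature index
(CTI, the median member STI), assemblage bias, warming magnitude,
immigration/extirpation percentages and Jaccard turnover, including
predictions at a stated warming such as +3 °C.

The package is aimed at paleoecologists and macroecologists working with
occurrence tables (e.g. Paleobiology Database downloads) binned to
ordered time bins, plus gridded paleotemperature fields. Every stage is
exposed as a pipeable, tibble-in/tibble-out function; a synthetic-world
generator with known thermal optima, detection probabilities, and anoxia
masks makes the whole chain testable without any external data.

## What's inside

| Stage | Functions |
|---|---|
| Ingest & habitats | `read_occurrences()`, `categorize_habitat()`, `species_affinities()`, `compute_range_table()` |
| Temperature fields | `temperature_field()`, `read_field_csv()`, `sample_temperature()`, `downscale_bilinear()`, `compare_fields()` |
| Regions | `cluster_spatial()`, `cluster_ecological()`, `partition_agreement()`, `assign_regions()` |
| Thermal metrics | `species_sti()`, `regional_median_temperature()`, `thermal_bias()`, `assemblage_bias()`, `label_phases()` |
| Classification | `classify_occupancy()` (two-/three-timer), `attach_bias()`, `pool_levels()`, `summarize_assemblage()` |
| Inference | `fit_species_model()`, `per_context_slopes()`, `slope_vs_warming()`, `fit_assemblage_models()`, `predict_at_warming()` |
| Synthetic worlds | `world_config()`, `generate_world()`, `scenario_presets()`, `evaluate_preset()` |
| Orchestration | `run_pipeline()`, `sensitivity_matrix()`; `tidy()`/`glance()`/`autoplot()` methods throughout |

## A worked example

```r
library(thermalbias)

w <- generate_world(world_config(n_species = 300, seed = 7))
out <- run_pipeline(w$occurrences, w$fields, w$range_table,
                    config = pipeline_config(k_regions = 5,
                                             min_occ_per_bin = 10))
out$species_fit
#> Species occupancy-response model: level_pooled ~ thermal_bias
#> random intercepts: ..rg + ..tz
#>           term estimate std_error t_value  df   p_value
#> 1  (Intercept)   3.1032   0.09857   31.48 987 3.63e-151
#> 2 thermal_bias  -0.0705   0.00879   -8.02 987  3.05e-15
#> n = 989; R2 marginal = 0.079; conditional = 0.127
```

The negative thermal-bias coefficient is the gradient: each additional
degree of cold preference relative to ambient pushes a species ~0.07
levels toward extirpation/extinction across a warming boundary (the
world here warms ~9 °C over two pulses). Assemblage-level predictions at
a modern-relevant +3 °C of regional warming:

```r
out$predictions
#> # A tibble: 6 × 5
#>   response         delta_t prediction conf_low conf_high
#> 1 pct_originating        3      0.443  -0.0103     0.896
#> 2 pct_immigrating        3     36.5    30.4       42.6
#> 3 pct_extirpated         3     41.6    34.9       48.2
#> 4 pct_extinct            3      3.57    1.73       5.40
#> 5 jaccard_turnover       3      0.762   0.737      0.787
#> 6 bias_change            3     -1.27   -1.65      -0.901
```

Read: at +3 °C, ~42 % of a pre-existing assemblage is extirpated and
~37 % of the subsequent assemblage is newly immigrated in this synthetic
world (whose narrow-niche species churn faster than real faunas);
`bias_change` says each assemblage accrues about −0.4 °C of thermal bias
per degree of warming rather than re-equilibrating instantly.
`plot_bias_gradient(out$records, by_phase = TRUE)` draws the bias
box plots per response level, and `autoplot(out$slope_fit)` the
slope-vs-warming meta-regression.

See `vignettes/thermal-bias-methods.Rmd` for the models, their
assumptions, the synthetic world's design, and known limitations.

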