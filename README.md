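# maihda

Intersectional **MAIHDA** (multilevel analysis of individual
heterogeneity and discriminatory accuracy) for continuous mental-health
outcomes, built for the setting of two British birth cohorts (Next
Steps, born 1990, and the Millennium Cohort Study, born 2000–02)
surveyed with the same instruments: anxiety (GAD-2, 0–6), depressive
symptoms (PHQ-2, 0–6), loneliness (UCLA-3, 3–9) and life satisfaction
(ONS single item, 0–10).

The package is for epidemiologists and social scientists who want to
quantify how much outcome variation lies *between* intersectional strata
— the cells of cohort × birth sex × racial/ethnic group × sexual
orientation (40 strata), optionally × a binary socioeconomic indicator
(80 strata) — and how much of that is explained by additive main
effects versus genuinely intersectional (stratum-specific) deviations.

## The model

For person *i* in stratum *j*:

```
y_ij = x_ij' β + u_j + e_ij ,   u_j ~ N(0, σ²_u),  e_ij ~ N(0, σ²_e)
```

* **VPC** = σ²_u / (σ²_u + σ²_e): the share of variance between strata
  ("discriminatory accuracy" of the classification), from an
  intercepts-only and a main-effects model.
* **PCV** = (1 − VPC_main / VPC_null) × 100: the percentage of
  between-stratum variance explained by the additive main effects.
* **Intersectional effects**: the stratum residuals u_j of the main
  model, with 95% credible intervals (Bayesian fit) or as point-only
  empirical-Bayes residuals (ML fit).

Estimation is by a conjugate Gibbs sampler with diffuse priors
(unweighted) and by survey-weighted pseudo maximum likelihood — the two
strategies used in practice for these designs. A synthetic two-cohort
generator with covariate-dependent non-response stands in for the
restricted survey data, so the entire pipeline is testable end to end.

## Worked example

```r
library(maihda)

spec    <- default_population_spec()          # 4167 + 4421 respondents
records <- generate_population(spec, seed = 2026)
strata  <- assign_strata(records, stratification("S40"), "gad2")
unlist(occupancy_report(strata))
#>        min_n        max_n pct_at_least      n_empty   n_occupied
#>          2.0       1773.0         62.5          0.0         40.0

cfg      <- mcmc_config_reduced(seed = 2026)  # 2000 iters; mcmc_config() = 50k
null_fit <- fit_maihda_mcmc(strata, "null", cfg)
main_fit <- fit_maihda_mcmc(strata, "main", cfg)
s        <- summarize_mcmc(main_fit, null_fit, strata)
s$decomposition[c("outcome", "stratification", "n_obs",
                  "vpc_null", "vpc_main", "pcv")]
#>   outcome stratification n_obs vpc_null vpc_main  pcv
#> 1    gad2            S40  8588   0.0919  0.00125 98.6
```

Occupancy is highly unequal (2 to 1,773 per stratum); 9.2% of anxiety
variance lies between strata before adjustment, and the additive main
effects account for 98.6% of it (PCV), leaving little genuinely
intersectional variation — as expected, since the default generator adds
only a small stratum-level deviation (SD 0.05). The per-stratum table is
caterpillar-plot-ready:

```r
head(s$strata[order(s$strata$residual),
              c("label", "n", "predicted", "residual",
                "residual_lower", "residual_upper")], 3)
#>    label    n predicted residual residual_lower residual_upper
#> 31  2110 1773       2.7   -0.027          -0.13          0.043
#> 16  1131   20       3.3   -0.017          -0.13          0.076
#> 21  2010 1465       2.4   -0.017          -0.11          0.062
```

Labels are digit-coded (cohort, sex, ethnicity, orientation, and for
80-stratum schemes SEP): `"2110"` = MCS, female, White, heterosexual.
All residual intervals here straddle zero. The weighted-ML route
(`fit_maihda_ml(..., weighted = TRUE)`, `summarize_ml()`) produces the
same report with point-only residuals, and `fit_saturated()` plus
`contrast_with_maihda()` contrasts MAIHDA's shrunken residuals with the
raw cell deviations of a saturated interaction regression.
`run_maihda_pipeline()` orchestrates all outcomes × stratifications ×
engines into a single summary table plus per-stratum files and a
manifest.

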