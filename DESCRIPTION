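Package: maihda
Title: Intersectional MAIHDA for Mental-Health Outcomes in Two British Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multilevel analysis of individual heterogeneity and
    discriminatory accuracy (MAIHDA) for continuous mental-health outcomes
    across intersectional social strata. Builds digit-coded intersectional
    strata from cohort, birth sex, racial/ethnic group, sexual orientation
    and socioeconomic indicators; fits two-level Gaussian random-intercept
    models both by a conjugate Gibbs sampler with diffuse priors and by
    (optionally survey-weighted) pseudo maximum likelihood; decomposes
    variance into variance partition coefficients and the proportional
    change in variance; and reports stratum-level predicted values and
    shrunken intersectional-effect residuals with uncertainty. A synthetic
    two-cohort survey generator with covariate-dependent non-response
    emulates the structure of the restricted cohort data so the whole
    pipeline is testable without access to it.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
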