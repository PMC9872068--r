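---
title: "Intersectional MAIHDA: models, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intersectional MAIHDA: models, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Multilevel analysis of individual heterogeneity and discriminatory
accuracy (MAIHDA) treats intersectional strata — the cells of the full
cross-classification of social identity/position variables — as level-2
units of a two-level Gaussian random-intercept model,

$$ y_{ij} = \mathbf{x}_{ij}'\boldsymbol\beta + u_j + e_{ij}, \qquad
   u_j \sim N(0, \sigma^2_u), \quad e_{ij} \sim N(0, \sigma^2_e), $$

for person $i$ in stratum $j$. Here the strata cross two birth cohorts
(Next Steps, born 1990; Millennium Cohort Study, born 2000–02), birth sex,
five racial/ethnic groups, sexual orientation and optionally one binary
socioeconomic indicator, giving the `S40` scheme
($2\times2\times5\times2 = 40$ strata) and the `S80a/b/c` schemes
($\times 2 = 80$). Outcomes are four bounded mental-health scores treated
as continuous: GAD-2 and PHQ-2 (0–6), UCLA-3 loneliness (3–9) and ONS
life satisfaction (0–10). Strata carry digit-coded labels (cohort, sex,
ethnicity, orientation, SEP), e.g. `"2140"` is the MCS, female, Black,
heterosexual stratum.

Two model variants are fitted per outcome and scheme:

* the **intercepts-only ("null") model**, whose between-stratum variance
  captures all systematic differences across intersections;
* the **main-effects model**, whose fixed effects are the
  stratum-defining variables themselves, so the remaining $u_j$ are the
  **intersectional effects** — deviations of a stratum from the additive
  "sum of its parts".

The **variance partition coefficient** VPC $= \sigma^2_u / (\sigma^2_u +
\sigma^2_e)$ measures the discriminatory accuracy of the stratum
classification, and the **proportional change in variance**
$\mathrm{PCV} = (1 - \mathrm{VPC}_{main}/\mathrm{VPC}_{null}) \times 100$
is the share of between-stratum variance explained by the additive main
effects. PCVs are computed from unrounded VPCs; for Bayesian fits, from
the posterior-mean VPCs (per-draw VPC summaries are also available),
because single PCV values without intervals are the conventional report.

## Bayesian estimation

`fit_maihda_mcmc()` is a conjugate Gibbs sampler with a flat prior on
$\boldsymbol\beta$ and inverse-gamma(0.001, 0.001) priors on both
variances — the conventional diffuse default for this model class; the
hyperparameters are exposed in `mcmc_config()` because posteriors for
small variances are sensitive to them. The full conditionals are the
standard ones: multivariate normal for $\boldsymbol\beta$, independent
normals $u_j \sim N(m_j, v_j)$ with $v_j = (n_j/\sigma^2_e +
1/\sigma^2_u)^{-1}$ and $m_j = v_j \sum_{i \in j}(y_i -
\mathbf{x}_i'\boldsymbol\beta)/\sigma^2_e$, and inverse-gamma updates for
both variances. Every conditional depends on the data only through
per-stratum aggregates, so one iteration costs $O(p^2 + pJ)$ regardless
of sample size and the full 50,000-iteration reporting protocol
(burn-in 5,000, thinning 50, 900 retained draws) runs in seconds.

Starting values use OLS for $\boldsymbol\beta$ and $\sigma^2_e$ and a
one-way ANOVA method-of-moments estimate for $\sigma^2_u$ (floored at
1e-8 to avoid a degenerate first conditional); starting values only
affect burn-in. One chain is the default; multiple chains with distinct
seeds are supported, and effective sample sizes for the variances are
logged but not gating. Posterior summaries are means with 95% credible
intervals from the empirical 2.5/97.5 percentiles, using linear
interpolation between order statistics (`quantile()` type 7) — with a
few hundred retained draws the tail percentile is definition-sensitive,
so the definition is fixed and documented. A reduced preset
(`mcmc_config_reduced()`: 2,000 iterations, 500 burn-in, thin 5) is used
for simulations and tests.

Reference categories for the main-model dummies are NS/1990, male,
White, heterosexual and the advantaged SEP category; estimates are
invariant to this choice, labels are not.

## Weighted pseudo maximum likelihood

`fit_maihda_ml()` fits the same models by maximising a weighted marginal
log-likelihood in which each individual log-density contribution is
multiplied by its scaled non-response weight (level-1 pseudo-ML). Weights
are rescaled to sum to the analysed sample size; strata are analytic
constructs rather than sampling units, so level 2 is unweighted. Writing
$W_j$, $S_j$, $Q_j$ for the weighted per-stratum size, residual sum and
residual square sum, each stratum contributes

$$ -\tfrac{W_j}{2}\log(2\pi\sigma^2_e)
   - \frac{Q_j - S_j^2/W_j}{2\sigma^2_e}
   - \tfrac12 \log\!\Big(1 + \frac{W_j\sigma^2_u}{\sigma^2_e}\Big)
   - \frac{S_j^2/W_j}{2(\sigma^2_e + W_j \sigma^2_u)} , $$

the closed form of integrating the weighted normal product over $u_j$.
$\boldsymbol\beta$ is profiled out by weighted GLS at each evaluation and
the optimiser (`optim`, L-BFGS-B) works on log-variances to enforce
positivity; estimates of $\sigma^2_u$ below 1e-10 are reported as 0 with
a boundary flag, in which case the PCV based on a boundary null fit is
reported missing. ML (not REML) is the default; REML is available.
Empirical-Bayes residuals are $\hat u_j = \lambda_j \bar r_j$ with
shrinkage $\lambda_j = W_j\sigma^2_u/(W_j\sigma^2_u + \sigma^2_e)$; no
interval estimates accompany them under this estimation strategy (a
cluster bootstrap would be needed and is out of scope). Fixed-effect
standard errors come from the inverse observed information of the
pseudo-likelihood and are model-based, not design-based — an
acknowledged simplification. VPC intervals under ML are delta-method
intervals propagated from the numerical covariance of the log-variance
estimates.

## The synthetic cohort generator

The restricted cohort data cannot be redistributed, so
`generate_population()` emulates their statistical structure: two cohorts
of 4,167 and 4,421 respondents; highly unequal stratum occupancy driven
by realistic category prevalences (82% White, 10% sexual minority, and so
on), which reproduces the qualitative occupancy pattern of a handful of
observations in minority–minority intersections up to ~1,800 in the
largest stratum, with some intersections empty in smaller draws; additive
fixed effects on each outcome scale placing the younger cohort, women,
sexual-minority and disadvantaged respondents at higher symptom levels
(magnitudes of 0.05–0.8 scale points, chosen once as plausible for short
screening scales); a shared stratum-level deviation drawn once per
stratum (`sigma_u`, default 0.05 — small, since the motivating analyses
found intersectional effects near zero) plus optional explicit per-label
offsets; and individual Gaussian noise (`sigma_e` of 1.6–2.0 scale
points, giving null-model VPCs in the 0.05–0.10 range typical of this
literature). Outcomes are generated as Gaussian latents, optionally
rounded and clipped to their scales; the analysis models treat them as
continuous, matching the linear MAIHDA being emulated. An optional
per-outcome missing-completely-at-random rate emulates outcome-specific
missingness.

What the generator does **not** emulate: the true cohorts' joint
covariate distribution (categories are drawn independently within
cohort), measurement error structure, ordinal response styles, or
longitudinal waves. Passing tests therefore demonstrate correctness of
the estimation machinery under the model's own assumptions, not
substantive conclusions about the real cohorts.

Non-response is logistic on the identity/position categories with an
optional stratum-level offset (named offsets or a random offset SD);
responders receive inverse-propensity weights normalised to sum to the
number of responders. Stratum-level response offsets are what make
weighting move stratum-level results: weights then vary *between* strata,
so the weighted likelihood credits low-response strata with their
restored (larger) effective sizes while their observed means still carry
small-sample noise, inflating the between-stratum variance estimate
relative to the unweighted fit. The simulation demonstrating this uses a
stratum offset SD of 2.0 on the log-odds scale — response propensity has
to vary substantially between strata for the contrast to be visible
above estimation noise — together with a small `sigma_u` (0.15) and a
large `sigma_e` (1.6).

## Numerical and design notes

* **Estimability of single-stratum offsets.** A main-effects model
  absorbs part of any one stratum's offset into the fixed effects (its
  size-weighted projection onto the additive design). The estimable
  intersectional effect is the offset net of that projection, further
  shrunk by $\lambda_j$; recovery tests score against this projected
  quantity, not the raw offset.
* **Coverage and chain length.** Stratum-residual credible intervals are
  calibrated: across replicate simulations from a correctly specified
  additive model their coverage of the true stratum effects approaches
  95% as the chain grows (94.8% at 10,000 iterations). With the reduced
  preset's 300 retained draws, Monte-Carlo noise in the percentile
  endpoints lowers attained coverage by about 1%, a property of quantile
  estimation rather than of the sampler.
* **Posterior mean vs MLE.** With $J = 40$ strata the posterior mean of
  $\sigma^2_u$ under the diffuse prior sits a few hundredths (on the VPC
  scale) above the downward-biased MLE even at $n = 8{,}000$; the two
  engines agree to that order, and each recovers generating VPCs within
  its own uncertainty.
* **Degenerate inputs.** Empty strata are excluded from the
  random-effects design but retained in reports as unmapped
  intersections; rank-deficient main designs (a category absent from the
  analysed records) are an error naming the collinear columns; constant
  outcomes floor both variance initialisations.
* **Determinism.** All randomness flows from explicit seeds;
  per-combination streams in `run_maihda_pipeline()` are derived from
  the master seed by stable hashing so adding an outcome never perturbs
  another's results, and a config+seed pair reproduces a bundle
  byte-for-byte.
* **Problem sizes.** Simulation-based tests use full-size synthetic
  cohorts (8,588 records) where the quantity under test demands them
  (parameter recovery at $n = 8{,}000$, coverage over 100 replicates,
  weighted-contrast over 25 replicates) and cohorts of a few hundred to a
  few thousand elsewhere; the aggregate-statistics samplers make these
  sizes inexpensive.

## Limitations

Only Gaussian (linear) MAIHDA is implemented; logistic variants, weighted
Bayesian estimation, design-based (sandwich) variances, bootstrap
intervals for weighted residuals, measurement-equivalence assessment and
longitudinal extensions are out of scope. The per-stratum saturated
regression comparator (`fit_saturated()`) reports nominal p-values
without multiplicity correction, with per-cell sample sizes shown so that
estimates resting on a handful of observations are visible.
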