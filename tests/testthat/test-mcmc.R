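test_that("starting values come from OLS plus one-way ANOVA moments", {
  ## constant outcome: intercept = c, variances at the floor
  rec <- three_stratum_records(y = rep(2.5, 9), g = rep(1:3, each = 3))
  st <- assign_strata(rec, stratification("S40"), "gad2")
  init <- maihda_init(maihda_design(st, "null"))
  expect_equal(unname(init$beta), 2.5)
  expect_equal(init$sigma2_e, 1e-8)
  expect_equal(init$sigma2_u, 1e-8)
  expect_equal(init$u, rep(0, 3))

  ## balanced one-way layout: sigma2_u,0 equals (MSB - MSW) / n per group
  y <- c(1.0, 1.4, 0.9, 2.2, 2.6, 2.1, 3.3, 2.9, 3.4)
  g <- rep(1:3, each = 3)
  rec <- three_stratum_records(y = y, g = g)
  st <- assign_strata(rec, stratification("S40"), "gad2")
  init <- maihda_init(maihda_design(st, "null"))
  fit <- aov(y ~ factor(g))
  ms <- summary(fit)[[1]]$`Mean Sq`
  expect_equal(init$sigma2_u, (ms[1] - ms[2]) / 3, tolerance = 1e-10)
  ## null-variant OLS intercept is the grand mean
  expect_equal(unname(init$beta), mean(y))
})

test_that("full-conditional parameters match numerical-integration posteriors", {
  inst <- tiny_instance()
  design <- list(y = inst$y, X = inst$X, g = inst$g, labels = inst$labels)
  ss <- maihda:::.mcmc_suffstats(design)
  fc <- maihda:::.full_conditionals(ss, inst$state$beta, inst$state$u,
                                    inst$state$sigma2_u, inst$state$sigma2_e,
                                    inst$prior_shape, inst$prior_scale)

  nb <- num_beta_conditional(inst)
  expect_equal(unname(fc$beta$mean), nb$mean, tolerance = 1e-6)
  expect_equal(unname(fc$beta$cov), nb$cov, tolerance = 1e-6)

  for (j in 1:2) {
    nu <- num_u_conditional(inst, j)
    expect_equal(fc$u$mean[j], nu$mean, tolerance = 1e-6)
    expect_equal(fc$u$var[j], nu$var, tolerance = 1e-6)
  }

  su <- num_sigma2u_conditional(inst)
  imp <- invgamma_moments(fc$sigma2_u$shape, fc$sigma2_u$scale)
  expect_equal(imp$mean, su$mean, tolerance = 1e-6)
  expect_equal(imp$var, su$var, tolerance = 1e-6)

  se <- num_sigma2e_conditional(inst)
  imp <- invgamma_moments(fc$sigma2_e$shape, fc$sigma2_e$scale)
  expect_equal(imp$mean, se$mean, tolerance = 1e-6)
  expect_equal(imp$var, se$var, tolerance = 1e-6)
})

test_that("the hand-computed conjugate update for a two-residual stratum holds", {
  ## sigma2_u = 1, sigma2_e = 1, residuals {1, 1}:
  ## v = 1/(2/1 + 1/1) = 1/3, m = v * 2 / 1 = 2/3
  design <- list(y = c(1, 1), X = matrix(1, 2, 1), g = c(1L, 1L),
                 labels = "s1")
  ss <- maihda:::.mcmc_suffstats(design)
  fc <- maihda:::.full_conditionals(ss, beta = 0, u = 0,
                                    sigma2_u = 1, sigma2_e = 1,
                                    prior_shape = 3, prior_scale = 2)
  expect_equal(fc$u$mean, 2 / 3, tolerance = 1e-12)
  expect_equal(fc$u$var, 1 / 3, tolerance = 1e-12)
})

test_that("chain bookkeeping follows the iteration/burn-in/thinning protocol", {
  cfg <- mcmc_config()
  expect_equal(cfg$retained, 900)
  expect_error(mcmc_config(iterations = 100, burn_in = 200), "burn_in")

  rec <- generate_population(default_population_spec(n_per_cohort = 400),
                             seed = 3)
  st <- assign_strata(rec, stratification("S40"), "phq2")
  cfg <- mcmc_config(iterations = 300, burn_in = 100, thin = 4, seed = 7)
  fit <- fit_maihda_mcmc(st, "null", cfg)
  expect_equal(nrow(fit$beta), 50)
  expect_equal(ncol(fit$u), sum(!st$table$empty))
  expect_true(all(fit$sigma2_u > 0) && all(fit$sigma2_e > 0))

  fit2 <- fit_maihda_mcmc(st, "null", cfg)
  expect_identical(fit$beta, fit2$beta)
  expect_identical(fit$u, fit2$u)

  fit3 <- fit_maihda_mcmc(st, "null",
                          mcmc_config(iterations = 300, burn_in = 100,
                                      thin = 4, seed = 8))
  expect_false(identical(fit$sigma2_u, fit3$sigma2_u))
})

test_that("posterior_summary uses means and 2.5/97.5 interpolated percentiles", {
  s <- posterior_summary(rep(3.2, 50))
  expect_equal(s$estimate, 3.2)
  expect_equal(s$lower, 3.2)
  expect_equal(s$upper, 3.2)

  draws <- as.numeric(1:100)
  s <- posterior_summary(draws)
  ## type-7 oracle: x_h + (h - floor(h)) (x_{h+1} - x_h), h = (n-1)p + 1
  h <- 99 * 0.025 + 1
  expect_equal(s$lower, floor(h) + (h - floor(h)))
  h <- 99 * 0.975 + 1
  expect_equal(s$upper, floor(h) + (h - floor(h)))
  expect_equal(s$estimate, 50.5)

  rec <- generate_population(default_population_spec(n_per_cohort = 300),
                             seed = 5)
  st <- assign_strata(rec, stratification("S40"), "gad2")
  fit <- fit_maihda_mcmc(st, "null",
                         mcmc_config(iterations = 200, burn_in = 50,
                                     thin = 5, seed = 1))
  expect_error(posterior_summary(fit, "nonsense"), "unknown quantity")
  vs <- posterior_summary(fit, "vpc")
  expect_true(vs$lower <= vs$estimate && vs$estimate <= vs$upper)
})

test_that("conditional stratum means shrink monotonically toward the raw mean", {
  ## same mean residual, increasing stratum size: E[u_j | rest] rises
  ## toward the raw mean, its variance falls toward sigma2_e / n_j
  sizes <- c(2, 5, 20, 100, 5000)
  y <- unlist(lapply(sizes, function(n) rep(1.5, n)))
  g <- rep(seq_along(sizes), times = sizes)
  design <- list(y = y, X = matrix(1, length(y), 1), g = as.integer(g),
                 labels = paste0("s", seq_along(sizes)))
  ss <- maihda:::.mcmc_suffstats(design)
  fc <- maihda:::.full_conditionals(ss, beta = 0, u = rep(0, 5),
                                    sigma2_u = 0.4, sigma2_e = 1.1,
                                    prior_shape = 3, prior_scale = 2)
  expect_true(all(diff(fc$u$mean) > 0))
  expect_true(all(fc$u$mean < 1.5))
  expect_equal(fc$u$mean[5], 1.5, tolerance = 1e-2)
  expect_equal(fc$u$var[5], 1.1 / 5000, tolerance = 1e-3)
})

test_that("rank-deficient main designs are rejected with the collinear columns named", {
  rec <- generate_population(default_population_spec(n_per_cohort = 500),
                             seed = 9)
  rec$ethnicity <- "White"   # ethnicity dummies become all-zero columns
  st <- assign_strata(rec, stratification("S40"), "gad2")
  expect_error(maihda_design(st, "main"), "collinear.*ethnicity")
})
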