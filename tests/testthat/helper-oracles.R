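## Independent numerical oracles used across the suite. These never call
## into the package's analytic formulas: conditionals are integrated from
## first-principles densities and likelihoods are built from dnorm() plus
## numerical integration.

## --- small hand-built model instance (2 strata, 6 observations) --------

tiny_instance <- function() {
  list(
    y = c(1.2, 0.8, 1.5, 2.3, 2.0, 2.6),
    X = cbind(`(Intercept)` = 1, x = c(0, 1, 0, 1, 0, 1)),
    g = c(1L, 1L, 1L, 2L, 2L, 2L),
    labels = c("s1", "s2"),
    state = list(beta = c(1.0, 0.3), u = c(0.2, -0.1),
                 sigma2_u = 0.5, sigma2_e = 0.8),
    prior_shape = 3, prior_scale = 2
  )
}

## --- numerical full-conditional moments --------------------------------

## p(beta | u, sigma2_e) on a 2-D Simpson grid
num_beta_conditional <- function(inst) {
  y <- inst$y; X <- inst$X; g <- inst$g; st <- inst$state
  yc <- y - st$u[g]
  grid1 <- seq(mean(yc) - 8, mean(yc) + 8, length.out = 1601)
  grid2 <- seq(-8, 8, length.out = 1601)
  ## log density at (b1, b2): -sum((yc - b1 - b2 x)^2)/(2 s2e)
  x <- X[, 2]
  S0 <- length(yc); Sx <- sum(x); Sxx <- sum(x^2)
  Sy <- sum(yc); Sxy <- sum(x * yc); Syy <- sum(yc^2)
  qform <- outer(grid1, grid2, function(b1, b2)
    Syy - 2 * b1 * Sy - 2 * b2 * Sxy + b1^2 * S0 +
      2 * b1 * b2 * Sx + b2^2 * Sxx)
  logf <- -qform / (2 * st$sigma2_e)
  f <- exp(logf - max(logf))
  w1 <- simpson_weights(length(grid1)); w2 <- simpson_weights(length(grid2))
  W <- outer(w1, w2)
  Z <- sum(W * f)
  m1 <- sum(W * f * outer(grid1, rep(1, length(grid2)))) / Z
  m2 <- sum(W * f * outer(rep(1, length(grid1)), grid2)) / Z
  v1 <- sum(W * f * outer((grid1 - m1)^2, rep(1, length(grid2)))) / Z
  v2 <- sum(W * f * outer(rep(1, length(grid1)), (grid2 - m2)^2)) / Z
  cv <- sum(W * f * outer(grid1 - m1, grid2 - m2)) / Z
  list(mean = c(m1, m2), cov = matrix(c(v1, cv, cv, v2), 2))
}

simpson_weights <- function(n) {
  stopifnot(n %% 2 == 1)
  w <- rep(c(4, 2), length.out = n)
  w[1] <- w[n] <- 1
  w
}

## p(u_j | beta, variances) by 1-D quadrature
num_u_conditional <- function(inst, j) {
  y <- inst$y; X <- inst$X; g <- inst$g; st <- inst$state
  r <- y - drop(X %*% st$beta)
  rj <- r[g == j]
  dens <- function(u) vapply(u, function(ui)
    exp(sum(dnorm(rj - ui, 0, sqrt(st$sigma2_e), log = TRUE))) *
      dnorm(ui, 0, sqrt(st$sigma2_u)), numeric(1))
  Z <- integrate(dens, -20, 20, rel.tol = 1e-12)$value
  m <- integrate(function(u) u * dens(u), -20, 20, rel.tol = 1e-12)$value / Z
  v <- integrate(function(u) (u - m)^2 * dens(u), -20, 20,
                 rel.tol = 1e-12)$value / Z
  list(mean = m, var = v)
}

## p(sigma2_u | u) from prior x normal densities, by quadrature on (0, inf)
num_sigma2u_conditional <- function(inst) {
  st <- inst$state
  a <- inst$prior_shape; b <- inst$prior_scale
  dens <- function(v) vapply(v, function(vi)
    vi^(-(a + 1)) * exp(-b / vi) *
      prod(dnorm(st$u, 0, sqrt(vi))), numeric(1))
  Z <- integrate(dens, 0, Inf, rel.tol = 1e-12)$value
  m <- integrate(function(v) v * dens(v), 0, Inf, rel.tol = 1e-12)$value / Z
  v2 <- integrate(function(v) (v - m)^2 * dens(v), 0, Inf,
                  rel.tol = 1e-12)$value / Z
  list(mean = m, var = v2)
}

num_sigma2e_conditional <- function(inst) {
  y <- inst$y; X <- inst$X; g <- inst$g; st <- inst$state
  a <- inst$prior_shape; b <- inst$prior_scale
  res <- y - drop(X %*% st$beta) - st$u[g]
  dens <- function(v) vapply(v, function(vi)
    vi^(-(a + 1)) * exp(-b / vi) *
      prod(dnorm(res, 0, sqrt(vi))), numeric(1))
  Z <- integrate(dens, 0, Inf, rel.tol = 1e-12)$value
  m <- integrate(function(v) v * dens(v), 0, Inf, rel.tol = 1e-12)$value / Z
  v2 <- integrate(function(v) (v - m)^2 * dens(v), 0, Inf,
                  rel.tol = 1e-12)$value / Z
  list(mean = m, var = v2)
}

## inverse-gamma moments implied by (shape, scale)
invgamma_moments <- function(shape, scale) {
  list(mean = scale / (shape - 1),
       var = scale^2 / ((shape - 1)^2 * (shape - 2)))
}

## --- weighted marginal likelihood by numerical integration -------------

## intercept-only model: each stratum's weighted contribution is
## integral over u of prod_i dnorm(y_i - beta - u)^(w_i) * dnorm(u; 0, s2u)
num_weighted_loglik <- function(y, g, w, beta, s2u, s2e) {
  ll <- 0
  for (j in sort(unique(g))) {
    rj <- y[g == j] - beta
    wj <- w[g == j]
    f <- function(u) vapply(u, function(ui)
      exp(sum(wj * dnorm(rj - ui, 0, sqrt(s2e), log = TRUE))) *
        dnorm(ui, 0, sqrt(s2u)), numeric(1))
    ll <- ll + log(integrate(f, -Inf, Inf, rel.tol = 1e-11)$value)
  }
  ll
}

## iterative grid refinement maximiser over (beta, log s2u, log s2e)
grid_search_ml <- function(y, g, w, beta_range, ls2u_range, ls2e_range,
                           points = 13, rounds = 7) {
  ranges <- list(beta_range, ls2u_range, ls2e_range)
  best <- NULL
  for (r in seq_len(rounds)) {
    grids <- lapply(ranges, function(rg) seq(rg[1], rg[2], length.out = points))
    vals <- expand.grid(b = grids[[1]], lu = grids[[2]], le = grids[[3]])
    ll <- mapply(function(b, lu, le)
      num_weighted_loglik(y, g, w, b, exp(lu), exp(le)),
      vals$b, vals$lu, vals$le)
    best <- vals[which.max(ll), ]
    steps <- vapply(grids, function(gd) gd[2] - gd[1], numeric(1))
    ranges <- list(c(best$b - steps[1], best$b + steps[1]),
                   c(best$lu - steps[2], best$lu + steps[2]),
                   c(best$le - steps[3], best$le + steps[3]))
  }
  list(beta = best$b, sigma2_u = exp(best$lu), sigma2_e = exp(best$le),
       loglik = max(ll))
}

## --- projection oracle --------------------------------------------------

## The estimable part of stratum-level offsets under a main-effects model:
## the true cell-mean vector with its size-weighted projection onto the
## additive dummy design removed. An offset at one stratum is partially
## absorbed by the fixed effects; only this residual is recoverable.
projection_residuals <- function(strata, mu_true) {
  occ <- strata$table[!strata$table$empty, ]
  vars <- names(strata$scheme$variables)
  fac <- occ[vars]
  for (v in vars) fac[[v]] <- factor(fac[[v]], levels = maihda:::.VARIABLES[[v]])
  X <- model.matrix(~ ., fac)
  fit <- lm.wfit(X, mu_true, w = occ$n)
  setNames(as.numeric(fit$residuals), occ$label)
}

## --- record builders ----------------------------------------------------

## records with 3 hand-chosen strata (all White/Het) and a given outcome
three_stratum_records <- function(y, g, w = NA_real_) {
  combos <- data.frame(
    cohort = c("NS", "NS", "MCS"),
    sex = c("M", "F", "M"),
    ethnicity = "White",
    orientation = "Het"
  )
  df <- combos[g, ]
  n <- length(y)
  df$person_id <- sprintf("P%03d", seq_len(n))
  df$sep_imd <- df$sep_tenure <- df$sep_childclass <- "advantaged"
  df$gad2 <- y
  df$phq2 <- df$ucla3 <- df$lifesat <- NA_real_
  df$weight <- rep(w, length.out = n)
  df$responded <- TRUE
  rownames(df) <- NULL
  df
}
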