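## Two-level Gaussian random-intercept MAIHDA by Gibbs sampling.
##
## Model: y_ij = x_ij' beta + u_j + e_ij, u_j ~ N(0, sigma2_u),
## e_ij ~ N(0, sigma2_e), with a flat prior on beta and inverse-gamma
## (shape, scale) priors on both variances. All full conditionals are
## conjugate, and every conditional depends on the data only through
## per-stratum aggregates (n_j, sums of y and x), so one Gibbs iteration
## costs O(p^2 + pJ) regardless of the number of respondents.

#' Build the fixed-effect design for a MAIHDA model
#'
#' The `"null"` (intercepts-only) variant has a single intercept column;
#' the `"main"` variant adds dummy codes for every non-reference category
#' of the stratum-defining variables (references: NS, Male, White,
#' Heterosexual, advantaged SEP).
#'
#' @param strata a `maihda_strata` from [assign_strata()].
#' @param variant `"null"` or `"main"`.
#' @return list with the response `y`, design `X`, stratum index `g`
#'   (integer over occupied strata), occupied `labels`, the J x p
#'   stratum-profile matrix `Xs`, and weights carried from the records.
#' @export
maihda_design <- function(strata, variant = c("main", "null")) {
  variant <- match.arg(variant)
  .assert(inherits(strata, "maihda_strata"), "strata must be a maihda_strata")
  data <- strata$data
  occupied <- strata$table$label[!strata$table$empty]
  .assert(length(occupied) >= 2, "need at least 2 occupied strata")
  g <- match(data$label, occupied)

  if (variant == "null") {
    X <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    vars <- names(strata$scheme$variables)
    fac <- data[vars]
    for (v in vars) fac[[v]] <- factor(fac[[v]], levels = .VARIABLES[[v]])
    X <- stats::model.matrix(~ ., data = fac)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      stop("rank-deficient design; collinear columns: ",
           paste(drop, collapse = ", "), call. = FALSE)
    }
  }
  ## stratum profile: covariates are constant within a stratum
  Xs <- X[match(occupied, data$label), , drop = FALSE]
  rownames(Xs) <- occupied

  list(y = data$y, X = X, g = g, labels = occupied, Xs = Xs,
       weights = data$weight, variant = variant,
       outcome = strata$outcome, scheme = strata$scheme$name,
       n_obs = nrow(data))
}

## Per-stratum aggregates sufficient for every Gibbs conditional.
.mcmc_suffstats <- function(design) {
  X <- design$X; y <- design$y; g <- design$g
  J <- length(design$labels)
  list(
    n = nrow(X), p = ncol(X), J = J,
    XtX = crossprod(X),
    Xty = drop(crossprod(X, y)),
    yty = sum(y^2),
    nj = as.numeric(tabulate(g, J)),
    Sy = as.numeric(rowsum(y, g)),
    G = rowsum(X, g)               # J x p: column sums of X within stratum
  )
}

#' MCMC configuration
#'
#' Defaults follow the reporting protocol of the analysis: 50,000
#' iterations, 5,000 burn-in, thinning every 50 (900 retained draws), one
#' chain, inverse-gamma(0.001, 0.001) priors on both variances and a flat
#' prior on the fixed effects.
#'
#' @param iterations,burn_in,thin chain-length controls.
#' @param chains number of independent chains (seeds `seed`, `seed+1`, ...).
#' @param seed integer seed.
#' @param prior_shape,prior_scale inverse-gamma hyperparameters shared by
#'   both variance priors.
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 50000, burn_in = 5000, thin = 50,
                        chains = 1, seed = 1L,
                        prior_shape = 0.001, prior_scale = 0.001) {
  .assert(burn_in < iterations, "burn_in must be < iterations")
  .assert(thin >= 1, "thin must be >= 1")
  .assert(chains >= 1, "chains must be >= 1")
  .assert(prior_shape > 0 && prior_scale > 0, "prior hyperparameters must be > 0")
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 chains = as.integer(chains), seed = as.integer(seed),
                 prior_shape = prior_shape, prior_scale = prior_scale,
                 retained = as.integer(floor((iterations - burn_in) / thin))),
            class = "mcmc_config")
}

#' Reduced-scale MCMC preset
#'
#' 2,000 iterations, 500 burn-in, thinning every 5 (300 retained draws) —
#' the simulation/testing preset; see [mcmc_config()] for the full
#' reporting protocol.
#'
#' @param ... overrides passed to [mcmc_config()].
#' @return an `mcmc_config`.
#' @export
mcmc_config_reduced <- function(...) {
  args <- utils::modifyList(list(iterations = 2000, burn_in = 500, thin = 5),
                            list(...))
  do.call(mcmc_config, args)
}

#' Starting values for the Gibbs sampler
#'
#' Ordinary least squares on the fixed design gives the initial fixed
#' effects and residual variance; a one-way ANOVA method-of-moments
#' estimator on the OLS residuals gives the initial between-stratum
#' variance, floored at 1e-8; stratum effects start at zero.
#'
#' @param design from [maihda_design()].
#' @return list with `beta`, `sigma2_u`, `sigma2_e`, `u`.
#' @export
maihda_init <- function(design) {
  ss <- .mcmc_suffstats(design)
  fit <- lm.fit(design$X, design$y)
  beta <- fit$coefficients
  r <- fit$residuals
  dfres <- ss$n - ss$p
  .assert(dfres >= 2, "need at least 2 residual degrees of freedom")
  sigma2_e <- max(sum(r^2) / dfres, 1e-8)

  ## one-way ANOVA moments on residuals: (MSB - MSW) / n0
  J <- ss$J
  rbar_j <- as.numeric(rowsum(r, design$g)) / ss$nj
  rbar <- mean(r)
  msb <- sum(ss$nj * (rbar_j - rbar)^2) / (J - 1)
  msw <- sum((r - rbar_j[design$g])^2) / (ss$n - J)
  n0 <- (ss$n - sum(ss$nj^2) / ss$n) / (J - 1)
  sigma2_u <- max((msb - msw) / n0, 1e-8)

  list(beta = beta, sigma2_u = sigma2_u, sigma2_e = sigma2_e,
       u = rep(0, J))
}

## Analytic parameters of each full conditional at the current state.
## Kept separate from the sampling loop so they can be checked against
## numerical-integration posteriors.
.full_conditionals <- function(ss, beta, u, sigma2_u, sigma2_e,
                               prior_shape, prior_scale) {
  XtX_inv <- chol2inv(chol(ss$XtX))
  beta_mean <- as.numeric(XtX_inv %*% (ss$Xty - drop(crossprod(ss$G, u))))
  beta_cov <- sigma2_e * XtX_inv

  Rres <- as.numeric(ss$Sy - ss$G %*% beta) # per-stratum sum of (y - x'beta)
  v <- 1 / (ss$nj / sigma2_e + 1 / sigma2_u)
  m <- v * Rres / sigma2_e

  sse <- ss$yty - 2 * sum(beta * ss$Xty) - 2 * sum(u * ss$Sy) +
    2 * sum(u * drop(ss$G %*% beta)) +
    drop(crossprod(beta, ss$XtX %*% beta)) + sum(ss$nj * u^2)

  list(
    beta = list(mean = beta_mean, cov = beta_cov),
    u = list(mean = m, var = v),
    sigma2_u = list(shape = prior_shape + ss$J / 2,
                    scale = prior_scale + sum(u^2) / 2),
    sigma2_e = list(shape = prior_shape + ss$n / 2,
                    scale = prior_scale + max(sse, 0) / 2)
  )
}

#' Fit a MAIHDA model by Gibbs sampling
#'
#' Samples, in order, the fixed effects from their multivariate-normal
#' full conditional, each stratum effect from its normal full conditional,
#' and both variances from their inverse-gamma full conditionals.
#' Reproducible from the config seed; with multiple chains the retained
#' draws are stacked with a `chain` index.
#'
#' @param strata a `maihda_strata`.
#' @param variant `"main"` or `"null"`.
#' @param config an [mcmc_config()].
#' @return an object of class `maihda_mcmc` with draw matrices `beta`
#'   (draws x p), `u` (draws x J), vectors `sigma2_u`, `sigma2_e`, the
#'   occupied stratum `labels`, the stratum profile `Xs`, and effective
#'   sample size diagnostics for the variances.
#' @export
fit_maihda_mcmc <- function(strata, variant = c("main", "null"),
                            config = mcmc_config()) {
  variant <- match.arg(variant)
  .assert(inherits(config, "mcmc_config"), "config must be an mcmc_config")
  design <- maihda_design(strata, variant)
  ss <- .mcmc_suffstats(design)
  init <- maihda_init(design)

  R <- chol(ss$XtX)
  a <- config$prior_shape; b <- config$prior_scale
  keep <- config$retained
  p <- ss$p; J <- ss$J

  all_beta <- vector("list", config$chains)
  all_u <- vector("list", config$chains)
  all_s2u <- vector("list", config$chains)
  all_s2e <- vector("list", config$chains)

  for (ch in seq_len(config$chains)) {
    withr::local_seed(config$seed + ch - 1L)
    beta <- init$beta; u <- init$u
    s2u <- init$sigma2_u; s2e <- init$sigma2_e

    bdraws <- matrix(NA_real_, keep, p)
    udraws <- matrix(NA_real_, keep, J)
    s2udraws <- numeric(keep); s2edraws <- numeric(keep)
    k <- 0L

    XtX_inv_Xty <- backsolve(R, backsolve(R, ss$Xty, transpose = TRUE))
    GtX <- ss$G   # J x p

    for (it in seq_len(config$iterations)) {
      ## beta | u, sigma2_e ~ N((X'X)^-1 X'(y - Zu), sigma2_e (X'X)^-1)
      rhs <- ss$Xty - drop(crossprod(GtX, u))
      bhat <- backsolve(R, backsolve(R, rhs, transpose = TRUE))
      beta <- bhat + sqrt(s2e) * backsolve(R, rnorm(p))

      ## u_j | beta, variances
      Rres <- ss$Sy - drop(GtX %*% beta)
      v <- 1 / (ss$nj / s2e + 1 / s2u)
      u <- rnorm(J, v * Rres / s2e, sqrt(v))

      ## sigma2_u | u
      s2u <- 1 / rgamma(1, shape = a + J / 2, rate = b + sum(u^2) / 2)

      ## sigma2_e | beta, u
      sse <- ss$yty - 2 * sum(beta * ss$Xty) - 2 * sum(u * ss$Sy) +
        2 * sum(u * drop(GtX %*% beta)) +
        drop(crossprod(beta, ss$XtX %*% beta)) + sum(ss$nj * u^2)
      s2e <- 1 / rgamma(1, shape = a + ss$n / 2, rate = b + max(sse, 0) / 2)

      if (!all(is.finite(c(beta, u, s2u, s2e)))) {
        stop("non-finite Gibbs state at iteration ", it,
             "; sigma2_u=", s2u, " sigma2_e=", s2e, call. = FALSE)
      }
      if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0) {
        k <- k + 1L
        bdraws[k, ] <- beta; udraws[k, ] <- u
        s2udraws[k] <- s2u; s2edraws[k] <- s2e
      }
    }
    all_beta[[ch]] <- bdraws[seq_len(k), , drop = FALSE]
    all_u[[ch]] <- udraws[seq_len(k), , drop = FALSE]
    all_s2u[[ch]] <- s2udraws[seq_len(k)]
    all_s2e[[ch]] <- s2edraws[seq_len(k)]
  }

  beta <- do.call(rbind, all_beta)
  colnames(beta) <- colnames(design$X)
  u <- do.call(rbind, all_u)
  colnames(u) <- design$labels
  s2u <- unlist(all_s2u); s2e <- unlist(all_s2e)

  structure(list(
    beta = beta, u = u, sigma2_u = s2u, sigma2_e = s2e,
    labels = design$labels, Xs = design$Xs, variant = variant,
    outcome = design$outcome, scheme = design$scheme,
    n_obs = design$n_obs, nj = ss$nj, config = config, init = init,
    chain = rep(seq_len(config$chains), each = keep),
    diagnostics = list(ess_sigma2_u = .ess(s2u), ess_sigma2_e = .ess(s2e))
  ), class = "maihda_mcmc")
}

## crude initial-positive-sequence effective sample size
.ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1, 100), plot = FALSE)$acf[-1]
  neg <- which(rho < 0)
  if (length(neg)) rho <- rho[seq_len(neg[1] - 1)]
  n / (1 + 2 * sum(rho))
}

#' Summarise posterior draws
#'
#' Point estimate = posterior mean; interval = empirical 2.5 and 97.5
#' percentiles across the retained draws (linear interpolation between
#' order statistics, `quantile()` type 7).
#'
#' @param x a `maihda_mcmc` fit or a numeric vector/matrix of draws.
#' @param quantity for fits: one of `"beta"`, `"u"`, `"sigma2_u"`,
#'   `"sigma2_e"`, `"vpc"`.
#' @param ... unused.
#' @return data.frame with `term`, `estimate`, `lower`, `upper`.
#' @export
posterior_summary <- function(x, ...) UseMethod("posterior_summary")

#' @rdname posterior_summary
#' @export
posterior_summary.default <- function(x, ...) {
  .assert(is.numeric(x) && length(x) > 0, "draws must be non-empty numeric")
  if (is.matrix(x)) {
    est <- colMeans(x)
    qs <- apply(x, 2, quantile, probs = c(0.025, 0.975), type = 7,
                names = FALSE)
    data.frame(term = colnames(x) %||% as.character(seq_len(ncol(x))),
               estimate = est, lower = qs[1, ], upper = qs[2, ],
               row.names = NULL)
  } else {
    qs <- quantile(x, c(0.025, 0.975), type = 7, names = FALSE)
    data.frame(term = "draws", estimate = mean(x),
               lower = qs[1], upper = qs[2])
  }
}

#' @rdname posterior_summary
#' @export
posterior_summary.maihda_mcmc <- function(x, quantity = "sigma2_u", ...) {
  draws <- switch(quantity,
                  beta = x$beta,
                  u = x$u,
                  sigma2_u = x$sigma2_u,
                  sigma2_e = x$sigma2_e,
                  vpc = x$sigma2_u / (x$sigma2_u + x$sigma2_e),
                  stop("unknown quantity '", quantity, "'", call. = FALSE))
  out <- posterior_summary(draws)
  if (!is.matrix(draws)) out$term <- quantity
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
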