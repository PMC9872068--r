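## (Optionally weighted) pseudo maximum likelihood for the same two-level
## Gaussian model.
##
## Each individual's log-density contribution is multiplied by its scaled
## level-1 weight; strata (analytic constructs, not sampling units) are
## unweighted at level 2. Writing r_i = y_i - x_i'beta, and per stratum j
## W_j = sum w_i, S_j = sum w_i r_i, Q_j = sum w_i r_i^2, the weighted
## marginal log-likelihood is
##
##   l = sum_j [ -(W_j/2) log(2 pi s2e) - (Q_j - S_j^2/W_j)/(2 s2e)
##               - log(1 + W_j s2u/s2e)/2 - (S_j^2/W_j)/(2 (s2e + W_j s2u)) ]
##
## (the closed form of integrating the weighted normal product over the
## stratum effect). beta is profiled by weighted GLS at each variance
## evaluation; the optimiser runs on (log s2u, log s2e) to keep both
## positive. Empirical-Bayes residuals are u_hat_j = lambda_j S_j / W_j
## with shrinkage lambda_j = W_j s2u / (W_j s2u + s2e).

.ml_suffstats <- function(design, w) {
  X <- design$X; y <- design$y; g <- design$g
  J <- length(design$labels)
  list(
    n = nrow(X), p = ncol(X), J = J,
    XtWX = crossprod(X, X * w),
    XtWy = drop(crossprod(X, w * y)),
    Wyy = sum(w * y^2),
    W = as.numeric(rowsum(w, g)),
    t = as.numeric(rowsum(w * y, g)),
    s = rowsum(X * w, g)            # J x p: sum of w x within stratum
  )
}

## profiled beta and the information matrix A = X' Omega^-1 X
.ml_profile_beta <- function(ss, s2u, s2e) {
  cj <- s2u / (s2e * (s2e + ss$W * s2u))
  A <- ss$XtWX / s2e - crossprod(ss$s * cj, ss$s)
  bvec <- ss$XtWy / s2e - drop(crossprod(ss$s * cj, ss$t))
  beta <- drop(solve(A, bvec))
  list(beta = beta, A = A)
}

.ml_loglik <- function(ss, beta, s2u, s2e, reml = FALSE, A = NULL) {
  S <- ss$t - drop(ss$s %*% beta)
  Q_tot <- ss$Wyy - 2 * sum(beta * ss$XtWy) +
    drop(crossprod(beta, ss$XtWX %*% beta))
  ll <- -(sum(ss$W) / 2) * log(2 * pi * s2e) -
    (Q_tot - sum(S^2 / ss$W)) / (2 * s2e) -
    sum(log1p(ss$W * s2u / s2e)) / 2 -
    sum((S^2 / ss$W) / (2 * (s2e + ss$W * s2u)))
  if (reml) {
    if (is.null(A)) A <- .ml_profile_beta(ss, s2u, s2e)$A
    ll <- ll - determinant(A, logarithm = TRUE)$modulus / 2 +
      (ss$p / 2) * log(2 * pi)
  }
  as.numeric(ll)
}

#' Fit a MAIHDA model by (weighted) pseudo maximum likelihood
#'
#' Maximises the weighted marginal Gaussian log-likelihood with the fixed
#' effects profiled out by weighted generalised least squares, optimising
#' over log-variances with `optim(method = "L-BFGS-B")`. Weights, when
#' used, are rescaled to sum to the analysed sample size; strata are
#' unweighted. No interval estimates for the stratum residuals are
#' produced under this estimation strategy.
#'
#' @param strata a `maihda_strata` from [assign_strata()].
#' @param variant `"main"` or `"null"`.
#' @param weighted use the records' `weight` column (rescaled to sum to
#'   n); records with missing weights are excluded.
#' @param reml use the residual (restricted) likelihood instead of ML.
#' @return an object of class `maihda_ml`: fixed effects with model-based
#'   standard errors, `sigma2_u` / `sigma2_e`, log-likelihood, per-stratum
#'   EB residuals `u` and shrinkage factors `lambda`, weighted stratum
#'   sizes `W`, a `boundary` flag (variance estimate at zero), convergence
#'   metadata, and the 2 x 2 covariance of the log-variance estimates used
#'   for delta-method intervals.
#' @export
fit_maihda_ml <- function(strata, variant = c("main", "null"),
                          weighted = FALSE, reml = FALSE) {
  variant <- match.arg(variant)
  .assert(inherits(strata, "maihda_strata"), "strata must be a maihda_strata")

  st <- strata
  if (weighted) {
    keep <- !is.na(st$data$weight) & st$data$weight > 0
    .assert(any(keep), "no records with positive weights")
    if (!all(keep)) {
      st$data <- st$data[keep, , drop = FALSE]
      st$n_obs <- nrow(st$data)
      counts <- table(factor(st$data$label, levels = st$table$label))
      st$table$n <- as.integer(counts[st$table$label])
      st$table$empty <- st$table$n == 0L
    }
  }
  design <- maihda_design(st, variant)
  n <- design$n_obs
  w <- if (weighted) {
    ww <- st$data$weight
    ww * (n / sum(ww))
  } else rep(1, n)

  ss <- .ml_suffstats(design, w)
  .assert(ss$n - ss$p >= 1, "no residual degrees of freedom")

  init <- maihda_init(design)
  par0 <- log(c(max(init$sigma2_u, 1e-6), max(init$sigma2_e, 1e-6)))
  ll0 <- {
    pb <- .ml_profile_beta(ss, exp(par0[1]), exp(par0[2]))
    .ml_loglik(ss, pb$beta, exp(par0[1]), exp(par0[2]), reml, pb$A)
  }

  negll <- function(par) {
    s2u <- exp(par[1]); s2e <- exp(par[2])
    pb <- .ml_profile_beta(ss, s2u, s2e)
    -.ml_loglik(ss, pb$beta, s2u, s2e, reml, pb$A)
  }
  opt <- optim(par0, negll, method = "L-BFGS-B",
               lower = c(log(1e-12), log(1e-10)),
               upper = c(log(1e8), log(1e8)),
               control = list(factr = 1e3, pgtol = 1e-10, maxit = 500))
  .assert(opt$convergence %in% c(0, 52) || opt$value <= -ll0 + 1e-6,
          "ML optimiser failed to converge: ", opt$message)

  s2u <- exp(opt$par[1]); s2e <- exp(opt$par[2])
  boundary <- s2u < 1e-10
  if (boundary) s2u <- 0

  pb <- .ml_profile_beta(ss, s2u, s2e)
  beta <- pb$beta
  names(beta) <- colnames(design$X)
  se_beta <- sqrt(diag(solve(pb$A)))

  S <- ss$t - drop(ss$s %*% beta)
  lambda <- if (s2u > 0) ss$W * s2u / (ss$W * s2u + s2e) else rep(0, ss$J)
  rawres <- S / ss$W
  u <- lambda * rawres

  ## numerical hessian of -loglik on the log-variance scale
  H <- .num_hessian(negll, opt$par)
  vcov_logvar <- tryCatch(solve(H), error = function(e)
    matrix(NA_real_, 2, 2))
  grad <- .num_gradient(negll, opt$par)

  structure(list(
    beta = beta, se_beta = se_beta,
    sigma2_u = s2u, sigma2_e = s2e, boundary = boundary,
    logLik = -opt$value, logLik_init = ll0,
    u = stats::setNames(u, design$labels),
    lambda = stats::setNames(lambda, design$labels),
    raw_residual = stats::setNames(rawres, design$labels),
    W = stats::setNames(ss$W, design$labels),
    nj = stats::setNames(as.numeric(tabulate(design$g, ss$J)), design$labels),
    labels = design$labels, Xs = design$Xs, variant = variant,
    outcome = design$outcome, scheme = design$scheme, n_obs = n,
    weighted = weighted, reml = reml,
    vcov_logvar = vcov_logvar,
    convergence = list(code = opt$convergence, counts = opt$counts,
                       gradient_norm = sqrt(sum(grad^2)),
                       message = opt$message)
  ), class = "maihda_ml")
}

.num_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

.num_hessian <- function(f, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i < p) for (j in (i + 1):p) {
      ej <- numeric(p); ej[j] <- h
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

#' Empirical-Bayes stratum residuals and predicted values
#'
#' @param fit a `maihda_ml` from [fit_maihda_ml()].
#' @return data.frame per occupied stratum: `label`, `n`, weighted size
#'   `W`, shrinkage `lambda`, raw mean residual, EB `residual`, additive
#'   `expected` value and `predicted` (= expected + residual). No interval
#'   columns: this estimation strategy does not provide them.
#' @export
eb_residuals <- function(fit) {
  .assert(inherits(fit, "maihda_ml"), "fit must be a maihda_ml")
  expected <- drop(fit$Xs %*% fit$beta)
  data.frame(
    label = fit$labels,
    n = as.integer(fit$nj),
    W = as.numeric(fit$W),
    lambda = as.numeric(fit$lambda),
    raw_residual = as.numeric(fit$raw_residual),
    residual = as.numeric(fit$u),
    expected = as.numeric(expected),
    predicted = as.numeric(expected + fit$u),
    row.names = NULL
  )
}
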