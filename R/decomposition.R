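## Variance partition coefficient (VPC), proportional change in variance
## (PCV), and the stratum-level report objects.

#' Variance partition coefficient
#'
#' Proportion of total outcome variance attributable to between-stratum
#' differences: `sigma2_u / (sigma2_u + sigma2_e)`. Vectorised (e.g. over
#' posterior draws).
#'
#' @param sigma2_u between-stratum variance (>= 0).
#' @param sigma2_e within-stratum residual variance.
#' @return numeric in `[0, 1]`.
#' @export
vpc <- function(sigma2_u, sigma2_e) {
  .assert(all(sigma2_u >= 0), "sigma2_u must be >= 0")
  .assert(all(sigma2_e >= 0), "sigma2_e must be >= 0")
  .assert(all(sigma2_u + sigma2_e > 0),
          "VPC undefined when both variances are zero")
  sigma2_u / (sigma2_u + sigma2_e)
}

#' Proportional change in variance
#'
#' Percentage of between-stratum variance accounted for by the additive
#' main effects: `(1 - vpc_main / vpc_null) * 100`.
#'
#' @param vpc_null VPC of the intercepts-only model (> 0).
#' @param vpc_main VPC of the main-effects model (>= 0).
#' @return percentage (at most 100; negative if the main model has the
#'   larger VPC).
#' @export
pcv <- function(vpc_null, vpc_main) {
  .assert(all(vpc_main >= 0), "vpc_main must be >= 0")
  .assert(all(vpc_null > 0), "PCV undefined when vpc_null is zero")
  (1 - vpc_main / vpc_null) * 100
}

.interval_cols <- function(summ, prefix) {
  stats::setNames(summ[c("estimate", "lower", "upper")],
                  paste0(prefix, c("", "_lower", "_upper")))
}

#' Summarise a pair of MCMC fits into report objects
#'
#' Per stratum and per retained draw the additive expected value is
#' `x_j' beta`, the intersectional effect is `u_j` and the predicted value
#' their sum; each is then summarised by its posterior mean and 2.5/97.5
#' percentiles. VPCs are computed per draw in each model; the single PCV
#' is taken from the posterior-mean VPCs.
#'
#' @param main_fit,null_fit `maihda_mcmc` fits of the `"main"` and
#'   `"null"` variants on the same strata.
#' @param strata the `maihda_strata` both models were fitted to.
#' @return list of class `maihda_summary` with `strata` (one row per
#'   occupied stratum: n, observed mean, expected, predicted and residual
#'   with interval bounds) and `decomposition` (one report row with
#'   n obs, both VPCs with intervals and the PCV).
#' @export
summarize_mcmc <- function(main_fit, null_fit, strata) {
  .assert(inherits(main_fit, "maihda_mcmc") && main_fit$variant == "main",
          "main_fit must be a main-variant maihda_mcmc")
  .assert(inherits(null_fit, "maihda_mcmc") && null_fit$variant == "null",
          "null_fit must be a null-variant maihda_mcmc")
  .assert(identical(main_fit$labels, null_fit$labels),
          "strata mismatch between main and null fits")
  occ <- strata$table[!strata$table$empty, , drop = FALSE]
  .assert(identical(main_fit$labels, occ$label),
          "strata mismatch between draws and table")

  expected_draws <- main_fit$beta %*% t(main_fit$Xs)   # draws x J
  predicted_draws <- expected_draws + main_fit$u

  es <- posterior_summary(expected_draws)
  ps <- posterior_summary(predicted_draws)
  rs <- posterior_summary(main_fit$u)

  strata_df <- data.frame(
    occ[setdiff(names(occ), c("empty"))],
    expected = es$estimate,
    predicted = ps$estimate, predicted_lower = ps$lower,
    predicted_upper = ps$upper,
    residual = rs$estimate, residual_lower = rs$lower,
    residual_upper = rs$upper,
    row.names = NULL
  )

  vn <- vpc(null_fit$sigma2_u, null_fit$sigma2_e)
  vm <- vpc(main_fit$sigma2_u, main_fit$sigma2_e)
  vn_s <- posterior_summary(vn); vm_s <- posterior_summary(vm)

  decomposition <- data.frame(
    outcome = main_fit$outcome,
    stratification = main_fit$scheme,
    estimation = "mcmc_unweighted",
    n_obs = main_fit$n_obs,
    vpc_null = vn_s$estimate, vpc_null_lower = vn_s$lower,
    vpc_null_upper = vn_s$upper,
    vpc_main = vm_s$estimate, vpc_main_lower = vm_s$lower,
    vpc_main_upper = vm_s$upper,
    pcv = pcv(vn_s$estimate, vm_s$estimate),
    pcv_undefined = FALSE,
    row.names = NULL
  )
  structure(list(strata = strata_df, decomposition = decomposition),
            class = "maihda_summary")
}

#' Summarise a pair of ML fits into report objects
#'
#' As [summarize_mcmc()] but with point-only stratum residuals (interval
#' columns are `NA`: this estimation strategy does not provide them) and
#' delta-method 95% intervals for the VPCs, propagated from the numerical
#' covariance of the log-variance estimates.
#'
#' @param main_fit,null_fit `maihda_ml` fits of the two variants.
#' @param strata the `maihda_strata` both models were fitted to.
#' @return a `maihda_summary`; when the null fit's between-stratum
#'   variance is at the zero boundary the PCV is reported missing with
#'   `pcv_undefined = TRUE`.
#' @export
summarize_ml <- function(main_fit, null_fit, strata) {
  .assert(inherits(main_fit, "maihda_ml") && main_fit$variant == "main",
          "main_fit must be a main-variant maihda_ml")
  .assert(inherits(null_fit, "maihda_ml") && null_fit$variant == "null",
          "null_fit must be a null-variant maihda_ml")
  .assert(identical(main_fit$labels, null_fit$labels),
          "strata mismatch between main and null fits")
  occ <- strata$table[!strata$table$empty, , drop = FALSE]
  keep <- occ$label %in% main_fit$labels
  occ <- occ[keep, , drop = FALSE]
  .assert(identical(main_fit$labels, occ$label),
          "strata mismatch between fit and table")

  eb <- eb_residuals(main_fit)
  strata_df <- data.frame(
    occ[setdiff(names(occ), "empty")],
    expected = eb$expected,
    predicted = eb$predicted,
    predicted_lower = NA_real_, predicted_upper = NA_real_,
    residual = eb$residual,
    residual_lower = NA_real_, residual_upper = NA_real_,
    row.names = NULL
  )

  vpc_ci <- function(fit) {
    v <- if (fit$sigma2_u + fit$sigma2_e > 0)
      vpc(fit$sigma2_u, fit$sigma2_e) else NA_real_
    if (fit$boundary || !all(is.finite(fit$vcov_logvar))) {
      return(c(v, NA_real_, NA_real_))
    }
    ## VPC = plogis(log s2u - log s2e); gradient wrt (log s2u, log s2e)
    gr <- c(v * (1 - v), -v * (1 - v))
    se <- sqrt(max(drop(gr %*% fit$vcov_logvar %*% gr), 0))
    c(v, max(v - 1.96 * se, 0), min(v + 1.96 * se, 1))
  }
  vn <- vpc_ci(null_fit); vm <- vpc_ci(main_fit)
  undefined <- null_fit$boundary || vn[1] <= 0

  tag <- if (main_fit$weighted) "ml_weighted" else "ml_unweighted"
  decomposition <- data.frame(
    outcome = main_fit$outcome,
    stratification = main_fit$scheme,
    estimation = tag,
    n_obs = main_fit$n_obs,
    vpc_null = vn[1], vpc_null_lower = vn[2], vpc_null_upper = vn[3],
    vpc_main = vm[1], vpc_main_lower = vm[2], vpc_main_upper = vm[3],
    pcv = if (undefined) NA_real_ else pcv(vn[1], vm[1]),
    pcv_undefined = undefined,
    row.names = NULL
  )
  structure(list(strata = strata_df, decomposition = decomposition),
            class = "maihda_summary")
}
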