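## Saturated fixed-effects interaction regression: the conventional
## comparator to MAIHDA. Cell-means parameterisation over the occupied
## strata (identical fit to a full factor interaction, simpler degeneracy
## handling), with contrasts re-expressed against an explicit reference
## cell. Fitted cell means equal observed (weighted) cell means exactly.

#' Fit the saturated interaction regression
#'
#' Ordinary or weighted least squares on stratum (cell) indicators. Empty
#' cells are inestimable and dropped. Per-cell sample sizes are reported
#' so coefficients resting on very few observations are visible.
#'
#' @param strata a `maihda_strata` from [assign_strata()].
#' @param reference_cell label of the reference stratum (must be
#'   occupied); required, not defaulted.
#' @param weighted use the records' `weight` column (rescaled to sum to n).
#' @return an object of class `maihda_saturated`: per-cell table with the
#'   (weighted) mean, contrast vs the reference, standard error, two-sided
#'   p-value and n; plus the pooled residual variance and R².
#' @export
fit_saturated <- function(strata, reference_cell, weighted = FALSE) {
  .assert(inherits(strata, "maihda_strata"), "strata must be a maihda_strata")
  .assert(!missing(reference_cell), "reference_cell must be given explicitly")
  data <- strata$data
  if (weighted) {
    keep <- !is.na(data$weight) & data$weight > 0
    data <- data[keep, , drop = FALSE]
  }
  occupied <- sort(unique(data$label))
  if (!(reference_cell %in% occupied)) {
    stop("reference cell '", reference_cell, "' is empty; occupied cells ",
         "include: ", paste(utils::head(occupied, 5), collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(data)
  w <- if (weighted) data$weight * (n / sum(data$weight)) else rep(1, n)
  g <- factor(data$label, levels = occupied)

  W <- as.numeric(rowsum(w, g))
  mean_c <- as.numeric(rowsum(w * data$y, g)) / W
  nj <- as.integer(tabulate(g, length(occupied)))

  resid <- data$y - mean_c[as.integer(g)]
  J <- length(occupied)
  dfres <- n - J
  .assert(dfres >= 1, "no residual degrees of freedom in the saturated fit")
  sigma2 <- sum(w * resid^2) / dfres

  ref <- match(reference_cell, occupied)
  est <- mean_c - mean_c[ref]
  se <- sqrt(sigma2 * (1 / W + 1 / W[ref]))
  se[ref] <- 0
  tval <- ifelse(se > 0, est / se, 0)
  pval <- ifelse(se > 0, 2 * pt(-abs(tval), dfres), NA_real_)

  ybar <- sum(w * data$y) / sum(w)
  ss_tot <- sum(w * (data$y - ybar)^2)
  ss_between <- sum(W * (mean_c - ybar)^2)

  structure(list(
    cells = data.frame(label = occupied, n = nj, W = W, mean = mean_c,
                       estimate = est, se = se, p_value = pval,
                       row.names = NULL),
    reference_cell = reference_cell,
    sigma2 = sigma2, df_residual = dfres,
    r_squared = ss_between / ss_tot,
    n_obs = n, weighted = weighted,
    outcome = strata$outcome, scheme = strata$scheme$name
  ), class = "maihda_saturated")
}

#' Contrast saturated cell estimates with MAIHDA residuals
#'
#' Per stratum: the raw cell deviation (observed cell mean minus the
#' MAIHDA additive expectation), the MAIHDA intersectional-effect
#' residual, their ratio (the empirical shrinkage factor) and n. The
#' attached summary counts sign agreements and compares mean absolute
#' magnitudes: shrinkage makes the MAIHDA residuals smaller on average.
#'
#' @param sat a `maihda_saturated`.
#' @param summary a `maihda_summary` (from [summarize_mcmc()] or
#'   [summarize_ml()]) for the same outcome, scheme and data.
#' @return data.frame with one row per common stratum and an attribute
#'   `"summary"` (list: sign agreement rate, mean absolute raw deviation
#'   and residual).
#' @export
contrast_with_maihda <- function(sat, summary) {
  .assert(inherits(sat, "maihda_saturated"), "sat must be a maihda_saturated")
  .assert(inherits(summary, "maihda_summary"),
          "summary must be a maihda_summary")
  .assert(identical(sat$outcome, summary$decomposition$outcome) &&
            identical(sat$scheme, summary$decomposition$stratification),
          "mismatched outcome or stratification")
  sdf <- summary$strata
  .assert(all(sat$cells$label %in% sdf$label) &&
            all(sdf$label %in% sat$cells$label),
          "mismatched strata sets between saturated fit and summary")
  m <- match(sat$cells$label, sdf$label)

  raw_dev <- sat$cells$mean - sdf$expected[m]
  res <- sdf$residual[m]
  ratio <- ifelse(abs(raw_dev) > 1e-12, res / raw_dev, NA_real_)
  out <- data.frame(
    label = sat$cells$label,
    n = sat$cells$n,
    cell_mean = sat$cells$mean,
    expected = sdf$expected[m],
    raw_deviation = raw_dev,
    maihda_residual = res,
    shrinkage_ratio = ratio,
    row.names = NULL
  )
  attr(out, "summary") <- list(
    sign_agreement = mean(sign(raw_dev) == sign(res)),
    mean_abs_raw = mean(abs(raw_dev)),
    mean_abs_residual = mean(abs(res))
  )
  out
}
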