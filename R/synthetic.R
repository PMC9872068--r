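## Synthetic two-cohort survey generator.
##
## Emulates the structure the MAIHDA pipeline assumes: two birth cohorts
## (Next Steps, born 1990; Millennium Cohort Study, born 2000-02), four
## bounded mental-health outcomes, additive fixed effects of the stratum
## defining variables, shared stratum-level deviations ("intersectional
## effects"), and covariate-dependent non-response generating inverse
## propensity weights.

#' Specify a synthetic population
#'
#' Defines the generating model for [generate_population()]: category
#' prevalences, additive fixed effects on each outcome scale, the standard
#' deviation of shared stratum-level effects (`sigma_u`), the individual
#' residual standard deviation (`sigma_e`), optional explicit
#' intersectional offsets for named strata, and outcome bounds/rounding.
#'
#' Outcomes are generated as Gaussian latents
#' `y = grand_mean + additive fixed effects + u[stratum] + e`, with
#' `u ~ N(0, sigma_u^2)` drawn once per stratum (all members share it) plus
#' any explicit offset, and `e ~ N(0, sigma_e^2)` per person. With
#' `rounding = TRUE` the latent is rounded to the nearest integer and
#' clipped to the declared scale bounds.
#'
#' @param n_per_cohort integer vector of length 1 or 2: respondents per
#'   cohort (NS, MCS). Default `c(4167, 4421)`.
#' @param prevalences named list of per-variable probability vectors
#'   (names = category codes). Each entry may instead be a list with `NS`
#'   and `MCS` components for cohort-specific prevalences.
#' @param grand_mean named numeric over outcomes (`gad2`, `phq2`, `ucla3`,
#'   `lifesat`).
#' @param fixed_effects named list, one entry per variable, each a matrix
#'   with non-reference categories as rows and outcomes as columns giving
#'   additive effects in outcome-scale units.
#' @param sigma_u,sigma_e named numeric over outcomes: stratum-effect SD
#'   (>= 0) and residual SD (> 0).
#' @param explicit_intersectional_effects optional named list per outcome:
#'   named vector of offsets keyed by 4-digit stratum label (S40 coding).
#' @param outcome_bounds named list of `c(min, max)` per outcome.
#' @param rounding logical; discretise outcomes to their integer scales.
#' @param mcar_rate per-outcome (or scalar) probability of missing
#'   completely at random, applied after generation.
#' @param stratum_vars variables whose full crossing defines the strata
#'   that share a generated effect (default the four S40 variables).
#' @param seed default seed used by [generate_population()].
#' @return an object of class `population_spec`.
#' @seealso [default_population_spec()] for study-scale defaults.
#' @export
population_spec <- function(n_per_cohort = c(4167, 4421),
                            prevalences,
                            grand_mean,
                            fixed_effects = list(),
                            sigma_u,
                            sigma_e,
                            explicit_intersectional_effects = NULL,
                            outcome_bounds = .OUTCOME_BOUNDS,
                            rounding = TRUE,
                            mcar_rate = 0,
                            stratum_vars = c("cohort", "sex", "ethnicity",
                                             "orientation"),
                            seed = 1L) {
  n_per_cohort <- as.integer(rep(n_per_cohort, length.out = 2))
  .assert(all(is.finite(n_per_cohort)) && all(n_per_cohort > 0),
          "invalid spec: n_per_cohort must be positive")

  .assert(is.list(prevalences) && length(prevalences) > 0,
          "invalid spec: prevalences must be a non-empty list")
  for (v in names(prevalences)) {
    .assert(v %in% names(.VARIABLES),
            "invalid spec: prevalences for unknown variable '", v, "'")
    pv <- prevalences[[v]]
    pieces <- if (is.list(pv)) pv else list(pv)
    for (p in pieces) {
      .assert(all(p >= 0) && abs(sum(p) - 1) <= 1e-12,
              "invalid spec: prevalences for '", v,
              "' must be non-negative and sum to 1")
      .assert(!is.null(names(p)) && all(names(p) %in% .VARIABLES[[v]]),
              "invalid spec: prevalences for '", v,
              "' must be named with its category codes")
    }
  }
  .assert(all(c("cohort", "sex", "ethnicity", "orientation") %in%
                names(prevalences)),
          "invalid spec: prevalences must cover cohort, sex, ethnicity, orientation")

  grand_mean <- grand_mean[.OUTCOMES]
  .assert(all(is.finite(grand_mean)),
          "invalid spec: grand_mean must cover all four outcomes")
  sigma_u <- rep(sigma_u, length.out = 4)
  sigma_e <- rep(sigma_e, length.out = 4)
  names(sigma_u) <- names(sigma_e) <- .OUTCOMES
  .assert(all(sigma_u >= 0), "invalid spec: sigma_u must be >= 0")
  .assert(all(sigma_e > 0), "invalid spec: sigma_e must be > 0")

  for (v in names(fixed_effects)) {
    fe <- fixed_effects[[v]]
    .assert(v %in% names(.VARIABLES),
            "invalid spec: fixed_effects for unknown variable '", v, "'")
    .assert(is.matrix(fe) && all(rownames(fe) %in% .VARIABLES[[v]][-1]) &&
              all(.OUTCOMES %in% colnames(fe)),
            "invalid spec: fixed_effects for '", v,
            "' must be a (non-reference category) x outcome matrix")
  }

  for (o in .OUTCOMES) {
    b <- outcome_bounds[[o]]
    .assert(is.numeric(b) && length(b) == 2 && b[1] < b[2],
            "invalid spec: outcome_bounds for '", o, "' must satisfy min < max")
  }
  mcar_rate <- rep(mcar_rate, length.out = 4)
  names(mcar_rate) <- .OUTCOMES
  .assert(all(mcar_rate >= 0 & mcar_rate < 1),
          "invalid spec: mcar_rate must be in [0, 1)")

  structure(list(
    n_per_cohort = n_per_cohort,
    prevalences = prevalences,
    grand_mean = grand_mean,
    fixed_effects = fixed_effects,
    sigma_u = sigma_u,
    sigma_e = sigma_e,
    explicit_intersectional_effects = explicit_intersectional_effects,
    outcome_bounds = outcome_bounds,
    rounding = isTRUE(rounding),
    mcar_rate = mcar_rate,
    stratum_vars = stratum_vars,
    seed = as.integer(seed)
  ), class = "population_spec")
}

#' Default study-scale synthetic population
#'
#' Cohort sizes 4167 (NS) and 4421 (MCS); plausible UK-cohort category
#' prevalences; additive fixed effects placing the younger cohort, women,
#' sexual-minority and socioeconomically disadvantaged respondents at
#' higher symptom levels; a small shared stratum-effect SD so that most
#' between-stratum variance is additive. Override any field via `...`.
#'
#' @param ... named overrides passed to [population_spec()].
#' @return a `population_spec`.
#' @export
default_population_spec <- function(...) {
  fe <- function(...) {
    rows <- list(...)
    m <- do.call(rbind, rows)
    colnames(m) <- .OUTCOMES
    m
  }
  defaults <- list(
    n_per_cohort = c(4167, 4421),
    prevalences = list(
      cohort = c(NS = 4167, MCS = 4421) / 8588,
      sex = c(M = 0.45, F = 0.55),
      ethnicity = c(White = 0.82, Mixed = 0.04, SouthAsian = 0.07,
                    Black = 0.03, Other = 0.04),
      orientation = c(Het = 0.90, SexMin = 0.10),
      sep_imd = c(advantaged = 0.5, disadvantaged = 0.5),
      sep_tenure = c(advantaged = 0.55, disadvantaged = 0.45),
      sep_childclass = c(advantaged = 0.5, disadvantaged = 0.5)
    ),
    grand_mean = c(gad2 = 1.6, phq2 = 1.6, ucla3 = 5.0, lifesat = 6.5),
    fixed_effects = list(
      cohort = fe(MCS = c(0.35, 0.35, 0.40, -0.50)),
      sex = fe(F = c(0.50, 0.35, 0.15, -0.10)),
      ethnicity = fe(Mixed = c(0.15, 0.15, 0.15, -0.15),
                     SouthAsian = c(0.05, 0.10, 0.10, -0.10),
                     Black = c(0.05, 0.15, 0.20, -0.20),
                     Other = c(0.10, 0.10, 0.10, -0.10)),
      orientation = fe(SexMin = c(0.80, 0.70, 0.60, -0.60)),
      sep_imd = fe(disadvantaged = c(0.25, 0.30, 0.20, -0.30)),
      sep_tenure = fe(disadvantaged = c(0.25, 0.30, 0.25, -0.30)),
      sep_childclass = fe(disadvantaged = c(0.20, 0.25, 0.15, -0.35))
    ),
    sigma_u = c(gad2 = 0.05, phq2 = 0.05, ucla3 = 0.05, lifesat = 0.05),
    sigma_e = c(gad2 = 1.6, phq2 = 1.6, ucla3 = 1.7, lifesat = 2.0)
  )
  args <- defaults
  overrides <- list(...)
  args[names(overrides)] <- overrides   # whole-field replacement, not a merge
  do.call(population_spec, args)
}

.additive_part <- function(df, spec, outcome) {
  mu <- rep(spec$grand_mean[[outcome]], nrow(df))
  for (v in names(spec$fixed_effects)) {
    if (is.null(df[[v]])) next
    fe <- spec$fixed_effects[[v]]
    idx <- match(df[[v]], rownames(fe))
    add <- ifelse(is.na(idx), 0, fe[idx, outcome])
    mu <- mu + add
  }
  mu
}

#' Generate a synthetic population
#'
#' Draws `n_per_cohort` records per cohort with independent category draws
#' from the prevalences, then builds each outcome as grand mean + additive
#' fixed effects + a shared stratum effect + individual Gaussian noise.
#' Fully reproducible from the seed. True stratum effects are attached as
#' `attr(., "stratum_effects")` (a per-outcome named vector keyed by
#' stratum label) so simulations can score recovery against the truth.
#'
#' @param spec a [population_spec()].
#' @param seed integer; defaults to `spec$seed`.
#' @return a data.frame of individual records (one row per person) with
#'   the canonical column layout used by [write_cohort()].
#' @export
generate_population <- function(spec, seed = spec$seed) {
  .assert(inherits(spec, "population_spec"), "spec must be a population_spec")
  withr::local_seed(seed)

  n <- spec$n_per_cohort
  cohort <- rep(c("NS", "MCS"), times = n)
  ntot <- sum(n)

  draw_cat <- function(v) {
    pv <- spec$prevalences[[v]]
    if (is.null(pv)) return(rep(NA_character_, ntot))
    if (is.list(pv)) {
      out <- character(ntot)
      for (co in c("NS", "MCS")) {
        idx <- cohort == co
        out[idx] <- sample(names(pv[[co]]), sum(idx), replace = TRUE,
                           prob = pv[[co]])
      }
      out
    } else {
      sample(names(pv), ntot, replace = TRUE, prob = pv)
    }
  }

  df <- data.frame(
    person_id = sprintf("%s%05d", cohort, unlist(lapply(n, seq_len))),
    cohort = cohort,
    stringsAsFactors = FALSE
  )
  for (v in c("sex", "ethnicity", "orientation", .SEP_VARS)) {
    df[[v]] <- draw_cat(v)
  }

  ## one shared effect per cell of the stratum_vars crossing, drawn for
  ## every possible cell so occupancy never changes the draw sequence
  scheme_codes <- lapply(spec$stratum_vars, function(v) .digit_codes(v))
  names(scheme_codes) <- spec$stratum_vars
  grid <- expand.grid(lapply(scheme_codes, names),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  all_labels <- sort(.encode_labels(grid, scheme_codes))
  rec_labels <- .encode_labels(df[spec$stratum_vars], scheme_codes)

  effects <- list()
  for (o in .OUTCOMES) {
    u <- stats::setNames(rnorm(length(all_labels), 0, spec$sigma_u[[o]]),
                         all_labels)
    extra <- spec$explicit_intersectional_effects[[o]]
    if (!is.null(extra)) {
      .assert(all(names(extra) %in% all_labels),
              "invalid spec: explicit_intersectional_effects labels unknown")
      u[names(extra)] <- u[names(extra)] + extra
    }
    effects[[o]] <- u

    y <- .additive_part(df, spec, o) + u[rec_labels] +
      rnorm(ntot, 0, spec$sigma_e[[o]])
    if (spec$rounding) {
      b <- spec$outcome_bounds[[o]]
      y <- pmin(pmax(round(y), b[1]), b[2])
    }
    if (spec$mcar_rate[[o]] > 0) {
      y[runif(ntot) < spec$mcar_rate[[o]]] <- NA_real_
    }
    df[[o]] <- as.numeric(y)
  }

  df$weight <- NA_real_
  df$responded <- TRUE
  df <- df[.DATASET_HEADER]
  attr(df, "stratum_effects") <- effects
  df
}

#' Specify a non-response model
#'
#' Response propensity is `plogis(intercept + sum of category log-odds +
#' stratum offset)`. Stratum offsets (keyed by 4-digit S40 label, or drawn
#' `N(0, stratum_offset_sd^2)` per stratum) let response vary at the
#' stratum level, which is what makes weighting move stratum-level results
#' more than fixed effects.
#'
#' @param intercept log-odds of responding at reference categories.
#' @param coefficients named list per variable: named numeric of per-category
#'   log-odds shifts (omitted categories contribute 0).
#' @param stratum_offsets optional named numeric keyed by stratum label.
#' @param stratum_offset_sd SD of random per-stratum response offsets
#'   (drawn inside [apply_nonresponse()]; ignored if `stratum_offsets` given).
#' @param weight_normalisation `"sum_to_n"` (weights sum to the number of
#'   responders) or `"mean_one"`.
#' @return an object of class `nonresponse_model`.
#' @export
nonresponse_model <- function(intercept = 0,
                              coefficients = list(),
                              stratum_offsets = NULL,
                              stratum_offset_sd = 0,
                              weight_normalisation = c("sum_to_n", "mean_one")) {
  weight_normalisation <- match.arg(weight_normalisation)
  .assert(is.finite(intercept), "intercept must be finite")
  for (v in names(coefficients)) {
    .assert(v %in% names(.VARIABLES), "unknown variable '", v, "'")
    .assert(all(is.finite(coefficients[[v]])),
            "coefficients for '", v, "' must be finite")
    .assert(all(names(coefficients[[v]]) %in% .VARIABLES[[v]]),
            "coefficients for '", v, "' must be named with category codes")
  }
  structure(list(
    intercept = intercept,
    coefficients = coefficients,
    stratum_offsets = stratum_offsets,
    stratum_offset_sd = stratum_offset_sd,
    weight_normalisation = weight_normalisation
  ), class = "nonresponse_model")
}

#' Apply non-response and construct inverse-propensity weights
#'
#' Each record responds with its logistic propensity; responders receive a
#' weight proportional to the inverse of that propensity, normalised per
#' the model's `weight_normalisation`. Non-responders keep their category
#' data but have all outcomes and the weight set to missing.
#'
#' @param records data.frame from [generate_population()].
#' @param model a [nonresponse_model()].
#' @param seed integer seed for the response draws.
#' @return the records with `responded` flags and `weight` filled in.
#' @export
apply_nonresponse <- function(records, model, seed = 1L) {
  .assert(inherits(model, "nonresponse_model"),
          "model must be a nonresponse_model")
  withr::local_seed(seed)
  n <- nrow(records)

  lp <- rep(model$intercept, n)
  for (v in names(model$coefficients)) {
    cf <- model$coefficients[[v]]
    idx <- match(records[[v]], names(cf))
    lp <- lp + ifelse(is.na(idx), 0, cf[idx])
  }

  s40 <- stratification("S40")
  labels <- .encode_labels(records[names(s40$variables)], s40$variables)
  offs <- model$stratum_offsets
  if (is.null(offs) && model$stratum_offset_sd > 0) {
    all_labels <- stratum_labels(s40)
    offs <- stats::setNames(
      rnorm(length(all_labels), 0, model$stratum_offset_sd), all_labels)
  }
  if (!is.null(offs)) {
    idx <- match(labels, names(offs))
    lp <- lp + ifelse(is.na(idx), 0, offs[idx])
  }

  p <- plogis(lp)
  responded <- runif(n) < p
  records$responded <- responded
  for (o in .OUTCOMES) records[[o]][!responded] <- NA_real_

  w <- rep(NA_real_, n)
  wr <- 1 / p[responded]
  wr <- switch(model$weight_normalisation,
               sum_to_n = wr * (sum(responded) / sum(wr)),
               mean_one = wr / mean(wr))
  w[responded] <- wr
  records$weight <- w
  records
}

#' Write a cohort dataset as delimited text
#'
#' One header row, one row per record, missing values as empty fields.
#' Round-trips losslessly through [read_cohort()].
#'
#' @param records data.frame with the canonical columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  .assert(nrow(records) > 0, "records must be non-empty")
  .assert(all(.DATASET_HEADER %in% names(records)),
          "records lack canonical columns")
  out <- records[.DATASET_HEADER]
  out$responded <- ifelse(is.na(out$responded), "",
                          ifelse(out$responded, "TRUE", "FALSE"))
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read a cohort dataset
#'
#' Validates the header and every categorical/numeric value, reporting the
#' offending row and column on failure; empty fields become missing.
#'
#' @param path CSV file written by [write_cohort()] (or matching its schema).
#' @return a data.frame of individual records.
#' @export
read_cohort <- function(path) {
  .assert(file.exists(path), "file not found: ", path)
  raw <- read.csv(path, colClasses = "character", na.strings = "",
                  check.names = FALSE)
  .assert(identical(names(raw), .DATASET_HEADER),
          "unknown or misordered columns; expected: ",
          paste(.DATASET_HEADER, collapse = ", "))
  .assert(nrow(raw) > 0, "no analysable records")

  for (v in c("cohort", "sex", "ethnicity", "orientation", .SEP_VARS)) {
    bad <- which(!is.na(raw[[v]]) & !(raw[[v]] %in% .VARIABLES[[v]]))
    .assert(length(bad) == 0,
            "unknown value '", raw[[v]][bad[1]], "' for variable '", v,
            "' at data row ", bad[1])
  }
  for (v in c(.OUTCOMES, "weight")) {
    num <- suppressWarnings(as.numeric(raw[[v]]))
    bad <- which(!is.na(raw[[v]]) & is.na(num))
    .assert(length(bad) == 0,
            "unparseable value '", raw[[v]][bad[1]], "' for column '", v,
            "' at data row ", bad[1])
    raw[[v]] <- num
  }
  resp <- raw$responded
  bad <- which(!is.na(resp) & !(resp %in% c("TRUE", "FALSE")))
  .assert(length(bad) == 0,
          "unparseable value for column 'responded' at data row ", bad[1])
  raw$responded <- resp == "TRUE"
  raw
}
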