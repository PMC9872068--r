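test_that("generation is deterministic and draws the declared structure", {
  spec <- default_population_spec(n_per_cohort = c(300, 400))
  a <- generate_population(spec, seed = 11)
  b <- generate_population(spec, seed = 11)
  expect_identical(a, b)

  expect_equal(nrow(a), 700)
  expect_equal(as.vector(table(a$cohort)[c("NS", "MCS")]), c(300, 400))
  expect_true(all(a$sex %in% c("M", "F")))
  expect_true(all(a$ethnicity %in%
                    c("White", "Mixed", "SouthAsian", "Black", "Other")))
  expect_true(all(a$orientation %in% c("Het", "SexMin")))

  c <- generate_population(spec, seed = 12)
  expect_false(identical(a$gad2, c$gad2))
})

test_that("invalid specs are rejected naming the offending field", {
  expect_error(default_population_spec(sigma_e = -1), "sigma_e")
  expect_error(default_population_spec(sigma_u = -0.1), "sigma_u")
  expect_error(default_population_spec(n_per_cohort = 0), "n_per_cohort")
  expect_error(
    default_population_spec(prevalences = list(
      cohort = c(NS = 0.6, MCS = 0.6),
      sex = c(M = 0.5, F = 0.5),
      ethnicity = c(White = 1),
      orientation = c(Het = 1))),
    "prevalences")
  expect_error(
    default_population_spec(outcome_bounds = list(
      gad2 = c(6, 0), phq2 = c(0, 6), ucla3 = c(3, 9), lifesat = c(0, 10))),
    "outcome_bounds")
})

test_that("with no stratum variation every stratum mean is the additive expectation", {
  ## only effects of the S80a-defining variables, so each stratum's
  ## expectation is exactly the sum of its categories' effects
  fe <- default_population_spec()$fixed_effects[
    c("cohort", "sex", "ethnicity", "orientation", "sep_imd")]
  spec <- default_population_spec(n_per_cohort = 3000, sigma_u = 0,
                                  sigma_e = 1e-9, rounding = FALSE,
                                  fixed_effects = fe)
  rec <- generate_population(spec, seed = 3)
  st <- assign_strata(rec, stratification("S80a"), "phq2")
  occ <- st$table[!st$table$empty, ]
  ## independent lookup of the additive expectation per stratum
  lookup <- function(var, cat) {
    m <- fe[[var]]
    ifelse(cat %in% rownames(m), m[match(cat, rownames(m)), "phq2"], 0)
  }
  expected <- spec$grand_mean[["phq2"]] +
    lookup("cohort", occ$cohort) + lookup("sex", occ$sex) +
    lookup("ethnicity", occ$ethnicity) +
    lookup("orientation", occ$orientation) + lookup("sep_imd", occ$sep_imd)
  expect_equal(occ$mean_observed, unname(expected), tolerance = 1e-6)
})

test_that("pooled mean of a pure-noise spec sits within 3 SE of the grand mean", {
  spec <- default_population_spec(n_per_cohort = 2000, fixed_effects = list(),
                                  sigma_u = 0, sigma_e = 1, rounding = FALSE)
  rec <- generate_population(spec, seed = 5)
  se <- 1 / sqrt(4000)
  for (o in c("gad2", "phq2", "ucla3", "lifesat")) {
    expect_lt(abs(mean(rec[[o]]) - spec$grand_mean[[o]]), 3 * se)
  }
})

test_that("between-stratum variance of generated data recovers sigma_u^2 (moments oracle)", {
  spec <- default_population_spec(n_per_cohort = 4000, fixed_effects = list(),
                                  sigma_u = 0.3, sigma_e = 0.9,
                                  rounding = FALSE)
  rec <- generate_population(spec, seed = 21)
  ## independent one-way ANOVA method-of-moments estimate on raw outcomes
  g <- interaction(rec$cohort, rec$sex, rec$ethnicity, rec$orientation,
                   drop = TRUE)
  n <- nrow(rec); J <- nlevels(g)
  nj <- as.numeric(table(g))
  ybar_j <- tapply(rec$gad2, g, mean)
  ybar <- mean(rec$gad2)
  msb <- sum(nj * (ybar_j - ybar)^2) / (J - 1)
  msw <- sum((rec$gad2 - ybar_j[g])^2) / (n - J)
  n0 <- (n - sum(nj^2) / n) / (J - 1)
  est <- (msb - msw) / n0
  ## realized var of 40 N(0, 0.09) draws has sd ~ 0.09 * sqrt(2/39)
  expect_lt(abs(est - 0.09), 3 * 0.09 * sqrt(2 / (J - 1)) + 0.01)
})

test_that("variance decomposes into fixed + stratum + residual parts", {
  spec <- default_population_spec(n_per_cohort = 4000, sigma_u = 0.3,
                                  sigma_e = 0.9, rounding = FALSE)
  rec <- generate_population(spec, seed = 8)
  mu <- maihda:::.additive_part(rec, spec, "gad2")
  total <- var(rec$gad2)
  parts <- var(mu) + 0.09 + 0.81
  expect_lt(abs(total - parts) / parts, 0.08)
})

test_that("rounded outcomes always lie inside their declared bounds", {
  bounds <- list(gad2 = c(0, 6), phq2 = c(0, 6), ucla3 = c(3, 9),
                 lifesat = c(0, 10))
  for (s in 1:5) {
    spec <- default_population_spec(
      n_per_cohort = 300,
      sigma_u = runif(1, 0, 2), sigma_e = runif(1, 0.5, 4),
      rounding = TRUE)
    rec <- generate_population(spec, seed = 100 + s)
    for (o in names(bounds)) {
      expect_true(all(rec[[o]] >= bounds[[o]][1] &
                        rec[[o]] <= bounds[[o]][2]))
      expect_true(all(rec[[o]] == round(rec[[o]])))
    }
  }
})

test_that("constant response propensity gives full response and equal weights", {
  rec <- generate_population(default_population_spec(n_per_cohort = 200),
                             seed = 2)
  out <- apply_nonresponse(rec, nonresponse_model(intercept = 20), seed = 9)
  expect_true(all(out$responded))
  expect_equal(out$weight, rep(1, nrow(out)))

  ## weighted and unweighted stratum means coincide under constant propensity
  st <- assign_strata(out, stratification("S40"), "gad2")
  wmean <- tapply(st$data$y * st$data$weight, st$data$label, sum) /
    tapply(st$data$weight, st$data$label, sum)
  expect_equal(as.numeric(wmean),
               as.numeric(tapply(st$data$y, st$data$label, mean)),
               tolerance = 1e-12)
})

test_that("zero-intercept response propensity is one half", {
  rec <- generate_population(default_population_spec(n_per_cohort = 2000),
                             seed = 2)
  out <- apply_nonresponse(rec, nonresponse_model(intercept = 0), seed = 10)
  p <- mean(out$responded)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / nrow(out)))
  expect_true(all(is.na(out$gad2[!out$responded])))
  expect_true(all(is.na(out$weight[!out$responded])))
  expect_true(all(out$weight[out$responded] > 0))
  expect_equal(sum(out$weight[out$responded]), sum(out$responded),
               tolerance = 1e-9)
})

test_that("penalised categories carry strictly larger weights", {
  rec <- generate_population(default_population_spec(n_per_cohort = 2000),
                             seed = 4)
  model <- nonresponse_model(
    intercept = 1,
    coefficients = list(orientation = c(SexMin = -1.5)))
  out <- apply_nonresponse(rec, model, seed = 12)
  resp <- out[out$responded, ]
  w_min <- resp$weight[resp$orientation == "SexMin"]
  w_het <- resp$weight[resp$orientation == "Het"]
  expect_true(min(w_min) > max(w_het))
})

test_that("datasets round-trip through CSV including missing fields", {
  spec <- default_population_spec(n_per_cohort = 60, mcar_rate = 0.15)
  rec <- generate_population(spec, seed = 31)
  rec <- apply_nonresponse(rec, nonresponse_model(intercept = 1), seed = 32)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(rec, path)
  expect_equal(length(readLines(path)), nrow(rec) + 1)
  back <- read_cohort(path)
  attr(rec, "stratum_effects") <- NULL
  rownames(rec) <- rownames(back) <- NULL
  expect_equal(back, rec)

  tiny <- rec[1:3, ]
  tiny$gad2[2] <- NA
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(tiny, path2)
  expect_equal(length(readLines(path2)), 4)
  expect_true(is.na(read_cohort(path2)$gad2[2]))
})
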