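## Intersectional strata: digit-coded labels and occupancy.
##
## Label convention (caterpillar-plot captions): first digit cohort
## (1 = NS/1990, 2 = MCS/2000-02), second birth sex (0 = Male, 1 = Female),
## third ethnicity (1 = White, 2 = Mixed, 3 = South Asian, 4 = Black,
## 5 = Other), fourth sexual orientation (0 = Heterosexual, 1 = Sexual
## minority), and for the 80-stratum schemes a fifth socioeconomic digit
## (0 = More deprived / Not owner / Manual, 1 = Less deprived / Owner /
## Non-manual).

.DIGITS <- list(
  cohort      = c(NS = "1", MCS = "2"),
  sex         = c(M = "0", F = "1"),
  ethnicity   = c(White = "1", Mixed = "2", SouthAsian = "3",
                  Black = "4", Other = "5"),
  orientation = c(Het = "0", SexMin = "1"),
  sep         = c(disadvantaged = "0", advantaged = "1")
)

.digit_codes <- function(v) {
  if (v %in% .SEP_VARS) .DIGITS$sep else .DIGITS[[v]]
}

## df: data.frame of category values in the variables' order;
## codes: named list variable -> named digit vector
.encode_labels <- function(df, codes) {
  out <- rep("", nrow(df))
  for (v in names(codes)) {
    digit <- codes[[v]][df[[v]]]
    out <- paste0(out, digit)
  }
  out
}

#' Define a stratification scheme
#'
#' `"S40"` crosses cohort, birth sex, ethnicity and sexual orientation
#' (2 x 2 x 5 x 2 = 40 strata); `"S80a"`, `"S80b"` and `"S80c"` append a
#' binary socioeconomic indicator (residential deprivation, housing
#' tenure, childhood social class respectively) for 80 strata.
#'
#' @param name one of `"S40"`, `"S80a"`, `"S80b"`, `"S80c"`.
#' @return an object of class `stratification` with the ordered variable
#'   list and digit codes.
#' @export
stratification <- function(name = c("S40", "S80a", "S80b", "S80c")) {
  name <- match.arg(name)
  vars <- c("cohort", "sex", "ethnicity", "orientation")
  sep_var <- switch(name, S40 = NULL, S80a = "sep_imd",
                    S80b = "sep_tenure", S80c = "sep_childclass")
  vars <- c(vars, sep_var)
  codes <- lapply(vars, .digit_codes)
  names(codes) <- vars
  structure(list(name = name, variables = codes, sep_var = sep_var),
            class = "stratification")
}

#' All possible stratum labels of a scheme
#'
#' @param scheme a [stratification()].
#' @return character vector of labels, sorted (40 or 80 of them).
#' @export
stratum_labels <- function(scheme) {
  .assert(inherits(scheme, "stratification"), "scheme must be a stratification")
  grid <- expand.grid(lapply(scheme$variables, names),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sort(.encode_labels(grid, scheme$variables))
}

#' Decode stratum labels back to categories
#'
#' @param labels character vector of digit-coded labels.
#' @param scheme a [stratification()].
#' @return data.frame with one column per defining variable.
#' @export
decode_strata <- function(labels, scheme) {
  .assert(inherits(scheme, "stratification"), "scheme must be a stratification")
  width <- length(scheme$variables)
  .assert(all(nchar(labels) == width),
          "labels must have ", width, " digits for scheme ", scheme$name)
  out <- data.frame(label = labels, stringsAsFactors = FALSE)
  for (k in seq_along(scheme$variables)) {
    v <- names(scheme$variables)[k]
    digit <- substr(labels, k, k)
    codes <- scheme$variables[[v]]
    idx <- match(digit, codes)
    .assert(!anyNA(idx), "undecodable digit for variable '", v, "'")
    out[[v]] <- names(codes)[idx]
  }
  out
}

#' Assign records to intersectional strata
#'
#' Performs listwise exclusion (per outcome): records missing any defining
#' variable or the outcome are dropped. Every retained record maps to
#' exactly one stratum; empty strata are flagged and excluded from model
#' fitting but kept in the table as unmapped intersections.
#'
#' @param records data.frame of individual records.
#' @param scheme a [stratification()].
#' @param outcome one of `"gad2"`, `"phq2"`, `"ucla3"`, `"lifesat"`.
#' @return an object of class `maihda_strata`: list with `data` (retained
#'   records with `y`, `weight`, `label`), `table` (all possible strata
#'   with decoded categories, `n`, observed mean, `empty` flag), `outcome`,
#'   `scheme`, `n_obs`.
#' @export
assign_strata <- function(records, scheme, outcome) {
  .assert(inherits(scheme, "stratification"), "scheme must be a stratification")
  .assert(outcome %in% .OUTCOMES, "unknown outcome '", outcome, "'")
  vars <- names(scheme$variables)
  .assert(all(c(vars, outcome) %in% names(records)),
          "records lack required columns")

  for (v in vars) {
    bad <- which(!is.na(records[[v]]) & !(records[[v]] %in% .VARIABLES[[v]]))
    .assert(length(bad) == 0,
            "unknown category value '", records[[v]][bad[1]],
            "' for variable '", v, "' at record ", bad[1])
  }

  keep <- stats::complete.cases(records[c(vars, outcome)])
  data <- records[keep, , drop = FALSE]
  .assert(nrow(data) > 0, "no analysable records")

  data$y <- data[[outcome]]
  data$label <- .encode_labels(data[vars], scheme$variables)

  all_labels <- stratum_labels(scheme)
  counts <- table(factor(data$label, levels = all_labels))
  means <- tapply(data$y, factor(data$label, levels = all_labels), mean)

  table <- decode_strata(all_labels, scheme)
  table$n <- as.integer(counts[all_labels])
  table$mean_observed <- as.numeric(means[all_labels])
  table$empty <- table$n == 0L

  structure(list(
    outcome = outcome,
    scheme = scheme,
    data = data,
    table = table,
    n_obs = nrow(data)
  ), class = "maihda_strata")
}

#' Stratum occupancy summary
#'
#' @param x a `maihda_strata` object (or its `table`).
#' @param threshold occupancy cutoff reported as a percentage of occupied
#'   strata at or above it (default 20).
#' @return list with `min_n`, `max_n`, `pct_at_least` (percentage of
#'   occupied strata with `n >= threshold`), `n_empty`, `n_occupied`,
#'   `threshold`.
#' @export
occupancy_report <- function(x, threshold = 20) {
  tab <- if (inherits(x, "maihda_strata")) x$table else x
  .assert(is.data.frame(tab) && "n" %in% names(tab), "not a stratum table")
  occ <- tab$n[tab$n > 0]
  list(
    min_n = if (length(occ)) min(occ) else NA_integer_,
    max_n = if (length(occ)) max(occ) else NA_integer_,
    pct_at_least = if (length(occ)) 100 * mean(occ >= threshold) else NA_real_,
    n_empty = sum(tab$n == 0),
    n_occupied = length(occ),
    threshold = threshold
  )
}
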