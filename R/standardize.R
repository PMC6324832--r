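# Crude and directly age-sex standardized areal prevalence per 100,000.
#
# Direct method: the standardized rate of code g is the weighted sum of its
# stratum-specific rates, with weights w_s = N_s / sum(N_s) taken from a
# reference population (here the national census aggregated over codes).
# Strata absent from a code (population 0) contribute 0 without weight
# re-normalization, keeping rates comparable across codes.

check_census <- function(census) {
  census <- data.table::as.data.table(census)
  if (any(census$population < 0)) stop("negative population", call. = FALSE)
  if (anyDuplicated(census[, .(geo_code, age_band, sex)]))
    stop("duplicate (geo_code, age_band, sex) rows in census", call. = FALSE)
  census
}

case_strata <- function(cases) {
  m <- data.table::copy(cases$members)
  m[, age_band := age_band_of(age)]
  if (anyNA(m$age_band)) stop("case ages below 18 cannot be standardized",
                              call. = FALSE)
  m
}

#' National stratum-specific rates per 100,000
#'
#' Aggregate case counts and populations over all codes by age band and sex,
#' producing the national age-sex prevalence profile (the data behind an
#' age-sex prevalence curve).
#'
#' @param cases A `case_set` from [select_cases()].
#' @param census Census table (`geo_code`, `age_band`, `sex`, `population`).
#' @return data.table: `age_band`, `sex`, `cases`, `population`,
#'   `rate` per 100,000.
#' @export
stratum_rates <- function(cases, census) {
  census <- check_census(census)
  pop <- census[, .(population = sum(population)), by = .(age_band, sex)]
  m <- case_strata(cases)
  cs <- m[, .(cases = .N), by = .(age_band, sex)]
  out <- merge(pop, cs, by = c("age_band", "sex"), all.x = TRUE)
  out[is.na(cases), cases := 0L]
  if (any(out$cases > 0 & out$population == 0))
    stop("stratum with cases but zero population", call. = FALSE)
  out[, rate := ifelse(population > 0, 1e5 * cases / population, NA_real_)]
  out[, age_band := factor(age_band, levels = age_band_levels())]
  data.table::setorder(out, age_band, sex)
  out[, .(age_band, sex, cases, population, rate)]
}

#' Directly age-sex standardized areal rates for one condition
#'
#' @param cases A `case_set`.
#' @param census Census table covering every code.
#' @param reference Reference population by the same strata (defaults to the
#'   national aggregate of `census`).
#' @return data.table per code: `geo_code`, `cases`, `crude`, `standardized`
#'   (both per 100,000; `NA` for codes with zero total population). The number
#'   of (code, stratum) cells skipped for zero population is attached as
#'   attribute `"empty_strata"`.
#' @export
direct_standardize <- function(cases, census, reference = NULL) {
  census <- check_census(census)
  if (is.null(reference)) reference <- census
  reference <- data.table::as.data.table(reference)
  ref <- reference[, .(N = sum(population)), by = .(age_band, sex)]
  ref[, w := N / sum(N)]

  m <- case_strata(cases)
  missing_codes <- setdiff(unique(m$geo_code), unique(census$geo_code))
  if (length(missing_codes))
    stop("case geo_code(s) absent from census: ",
         paste(head(missing_codes, 5), collapse = ", "), call. = FALSE)

  cell <- merge(
    census,
    m[, .(cases = .N), by = .(geo_code, age_band, sex)],
    by = c("geo_code", "age_band", "sex"), all.x = TRUE)
  cell[is.na(cases), cases := 0L]
  cell <- merge(cell, ref[, .(age_band, sex, w)], by = c("age_band", "sex"))
  empty <- cell[population == 0 & w > 0, .N]
  cell[, rate := ifelse(population > 0, cases / population, 0)]

  out <- cell[, .(cases = sum(cases),
                  population = sum(population),
                  standardized = 1e5 * sum(w * rate)), by = geo_code]
  out[, crude := ifelse(population > 0, 1e5 * cases / population, NA_real_)]
  out[population == 0, standardized := NA_real_]
  data.table::setorder(out, geo_code)
  res <- out[, .(geo_code, cases, crude, standardized)]
  data.table::setattr(res, "empty_strata", empty)
  res
}

#' National prevalence per 100,000
#'
#' Total unique cases over the total reference population. Equals the
#' population-weighted mean of the stratum rates when the reference is the
#' national census itself.
#'
#' @inheritParams stratum_rates
#' @return Scalar rate per 100,000.
#' @export
national_rate <- function(cases, census) {
  census <- check_census(census)
  total <- sum(census$population)
  if (total == 0) stop("zero national population", call. = FALSE)
  1e5 * nrow(cases$members) / total
}

#' Areal rates for both conditions in long format
#'
#' @param case_sets Named list of `case_set`s as returned by [select_cases()].
#' @param census Census table.
#' @param reference Optional reference population (default: national census).
#' @return data.table: `geo_code`, `condition`, `cases`, `crude`,
#'   `standardized`.
#' @export
areal_rates <- function(case_sets, census, reference = NULL) {
  out <- lapply(names(case_sets), function(cond) {
    r <- direct_standardize(case_sets[[cond]], census, reference)
    r[, condition := cond]
    r
  })
  data.table::rbindlist(out)[, .(geo_code, condition, cases, crude, standardized)]
}
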