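census_4strata <- function() {
  data.table::data.table(
    geo_code = rep(c("A", "B"), each = 4),
    age_band = rep(c("20-29", "20-29", "30-39", "30-39"), 2),
    sex = rep(c("F", "M"), 4),
    population = c(100L, 200L, 300L, 400L, 1000L, 1000L, 1000L, 1000L))
}

reference_4strata <- function() {
  data.table::data.table(
    geo_code = "REF",
    age_band = c("20-29", "20-29", "30-39", "30-39"),
    sex = c("F", "M", "F", "M"),
    population = c(250L, 250L, 250L, 250L))
}

test_that("direct_standardize matches hand arithmetic to 1e-12", {
  # code A: 1 case in (20-29, F), 3 cases in (30-39, M); equal ref weights
  cases <- make_case_set("obesity",
                         geo_code = c("A", "A", "A", "A"),
                         age = c(25, 35, 35, 35),
                         sex = c("F", "M", "M", "M"))
  out <- direct_standardize(cases, census_4strata(), reference_4strata())
  hand_A <- 1e5 * (0.25 * (1 / 100) + 0.25 * 0 + 0.25 * 0 + 0.25 * (3 / 400))
  expect_equal(out[geo_code == "A"]$standardized, hand_A, tolerance = 1e-12)
  expect_equal(out[geo_code == "A"]$crude, 1e5 * 4 / 1000, tolerance = 1e-12)
  expect_equal(out[geo_code == "B"]$standardized, 0)

  # 2-strata variant with weights (0.25, 0.75): rates (0.01, 0.03) -> 2,500
  cen <- data.table::data.table(geo_code = "A",
                                age_band = c("20-29", "30-39"),
                                sex = "F", population = c(100L, 100L))
  ref <- data.table::data.table(geo_code = "REF",
                                age_band = c("20-29", "30-39"),
                                sex = "F", population = c(250L, 750L))
  cs <- make_case_set("obesity", rep("A", 4), c(25, 35, 35, 35), rep("F", 4))
  out2 <- direct_standardize(cs, cen, ref)
  expect_equal(out2$standardized, 1e5 * (0.25 * 0.01 + 0.75 * 0.03),
               tolerance = 1e-12)
})

test_that("equal stratum rates collapse to that rate; self-reference gives crude", {
  cen <- census_4strata()[geo_code == "A"]
  # rate 0.02 in every stratum: cases 2, 4, 6, 8
  cs <- make_case_set("obesity",
                      rep("A", 20),
                      rep(c(25, 25, 35, 35), c(2, 4, 6, 8)),
                      rep(c("F", "M", "F", "M"), c(2, 4, 6, 8)))
  any_ref <- reference_4strata()
  out <- direct_standardize(cs, cen, any_ref)
  expect_equal(out$standardized, 1e5 * 0.02, tolerance = 1e-12)

  # reference equal to the code's own population: standardized == crude
  uneq <- make_case_set("obesity", rep("A", 5), c(25, 25, 35, 35, 35),
                        c("F", "F", "M", "M", "M"))
  self <- direct_standardize(uneq, cen, reference = cen)
  expect_equal(self$standardized, self$crude, tolerance = 1e-12)
})

test_that("standardized rates are invariant to uniform population scaling", {
  cen <- census_4strata()
  cs <- make_case_set("obesity", c("A", "A", "B"), c(25, 35, 25), c("F", "M", "M"))
  out1 <- direct_standardize(cs, cen, reference_4strata())
  cen2 <- data.table::copy(cen)[, population := population * 3L]
  cs2 <- make_case_set("obesity", rep(cs$members$geo_code, 3),
                       rep(cs$members$age, 3), rep(cs$members$sex, 3))
  out2 <- direct_standardize(cs2, cen2, reference_4strata())
  expect_equal(out1$standardized, out2$standardized, tolerance = 1e-12)
})

test_that("adding a case to a populated stratum strictly raises the rate", {
  cen <- census_4strata()
  cs <- make_case_set("obesity", c("A", "A"), c(25, 35), c("F", "M"))
  base <- direct_standardize(cs, cen, reference_4strata())
  cs2 <- make_case_set("obesity", c("A", "A", "A"), c(25, 35, 35),
                       c("F", "M", "F"))
  more <- direct_standardize(cs2, cen, reference_4strata())
  expect_gt(more[geo_code == "A"]$standardized,
            base[geo_code == "A"]$standardized)
})

test_that("zero-population codes carry missing rates, not zero", {
  cen <- rbind(census_4strata(),
               data.table::data.table(geo_code = "C", age_band = "20-29",
                                      sex = "F", population = 0L))
  cs <- make_case_set("obesity", "A", 25, "F")
  out <- direct_standardize(cs, cen, reference_4strata())
  expect_true(is.na(out[geo_code == "C"]$standardized))
  expect_true(is.na(out[geo_code == "C"]$crude))
})

test_that("stratum_rates and national_rate satisfy their identities", {
  cen <- census_4strata()
  # 10 cases / 100,000: put 10 cases in a stratum scaled to 100,000
  cen1 <- data.table::data.table(geo_code = "A", age_band = "20-29",
                                 sex = "F", population = 100000L)
  cs10 <- make_case_set("obesity", rep("A", 10), rep(25, 10), rep("F", 10))
  expect_equal(stratum_rates(cs10, cen1)$rate, 10)
  expect_equal(national_rate(cs10, cen1), 10)

  # national rate equals the reference-weighted stratum rates
  cs <- make_case_set("obesity", c("A", "A", "B", "B"), c(25, 35, 35, 25),
                      c("F", "M", "M", "M"))
  sr <- stratum_rates(cs, cen)
  w <- sr$population / sum(sr$population)
  expect_equal(national_rate(cs, cen), sum(w * sr$rate), tolerance = 1e-12)

  # scale invariance of the national rate
  cen2 <- data.table::copy(cen)[, population := population * 2L]
  cs2 <- make_case_set("obesity", rep(cs$members$geo_code, 2),
                       rep(cs$members$age, 2), rep(cs$members$sex, 2))
  expect_equal(national_rate(cs, cen), national_rate(cs2, cen2))

  # zero cases everywhere -> all-zero curve
  none <- make_case_set("obesity", character(0), numeric(0), character(0))
  expect_true(all(stratum_rates(none, cen)$rate == 0))

  # cases in an unpopulated stratum are an error
  cen0 <- data.table::data.table(geo_code = "A", age_band = "20-29",
                                 sex = "F", population = 0L)
  expect_error(stratum_rates(cs10, cen0), "zero population")
  expect_error(national_rate(cs10, cen0), "zero national population")
})
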