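test_that("config validation rejects degenerate worlds", {
  expect_error(sim_config(n_codes = 0), "n_codes")
  expect_error(sim_config(n_codes = 1), "n_codes")
  expect_error(sim_config(frailty_sd = -1), "frailty_sd")
  expect_error(sim_config(duplicate_rate = -0.1), "duplicate_rate")
  bad <- default_age_sex_structure()
  bad$share <- bad$share * 2
  expect_error(sim_config(age_sex_structure = bad), "sum to 1")
})

test_that("fixed seed fixes every emitted table byte-for-byte", {
  cfg <- sim_config(n_codes = 60, seed = 99)
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  p1 <- write_simulation(cfg, d1)
  p2 <- write_simulation(cfg, d2)
  for (f in names(p1))
    expect_identical(unname(tools::md5sum(p1[[f]])),
                     unname(tools::md5sum(p2[[f]])), label = f)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("degenerate log-normal gives identical code populations", {
  cfg <- sim_config(n_codes = 40, pop_log_sd = 0, seed = 3)
  tabs <- generate_areal_tables(cfg)
  totals <- tabs$census[, .(pop = sum(population)), by = geo_code]$pop
  expect_true(all(totals == totals[1]))
})

test_that("census and socio tables satisfy their contracts", {
  cfg <- sim_config(n_codes = 150, seed = 11)
  tabs <- generate_areal_tables(cfg)
  expect_equal(nrow(tabs$census), 150 * 18)
  expect_true(all(tabs$census$population >= 0))
  expect_false(anyDuplicated(tabs$census[, .(geo_code, age_band, sex)]) > 0)
  shares <- as.matrix(tabs$socio[, .(unemployment, blue_collar, low_diploma,
                                     immigrant, non_taxable)])
  expect_true(all(shares >= 0 & shares <= 1))
  expect_true(all(tabs$socio$typology %in% typology_levels()))
})

test_that("zero socio_corr yields uncorrelated latent scores at scale", {
  cfg <- sim_config(n_codes = 5000, socio_corr = 0, seed = 21)
  tabs <- generate_areal_tables(cfg)
  lat <- attr(tabs$socio, "latent")
  expect_lt(abs(cor(lat$z_social, lat$z_material)), 0.05)
})

test_that("duplicate_rate = 0 gives exactly one stay per case and condition", {
  cfg <- null_effect_config(n_codes = 50, seed = 5)
  tabs <- generate_areal_tables(cfg)
  st <- generate_stays(cfg, tabs$census, tabs$socio)
  per_patient <- st$stays[, .(n_stays = data.table::uniqueN(stay_id)),
                          by = patient_id]
  expect_true(all(per_patient$n_stays == 1L))
})

test_that("total generated cases equals the recorded ground truth", {
  cfg <- sim_config(n_codes = 80, seed = 17)
  tabs <- generate_areal_tables(cfg)
  st <- generate_stays(cfg, tabs$census, tabs$socio)
  agg <- st$truth$cases_by_code[, .(total = sum(cases)), by = condition]
  expect_equal(agg[condition == "obesity"]$total,
               unname(st$truth$n_cases["obesity"]))
  expect_equal(agg[condition == "depression"]$total,
               unname(st$truth$n_cases["depression"]))
})

test_that("with all effects off, stratum prevalence matches the baseline logit", {
  # large populations, single-code world scaled down: total pop ~ 2e6
  cfg <- null_effect_config(n_codes = 100, seed = 31,
                            pop_log_mean = log(20000), pop_log_sd = 0)
  tabs <- generate_areal_tables(cfg)
  st <- generate_stays(cfg, tabs$census, tabs$socio)
  sel <- select_cases(st$stays)
  sr <- stratum_rates(sel$obesity, tabs$census)
  base <- default_baseline_logits()
  chk <- merge(sr, base[, .(age_band, sex, expected = 1e5 * plogis(obesity))],
               by = c("age_band", "sex"))
  # 5-sigma binomial band per stratum
  chk[, tol := 5 * 1e5 * sqrt(plogis(base$obesity[1]) / population)]
  chk[, tol := 5 * 1e5 * sqrt((expected / 1e5) * (1 - expected / 1e5) / population)]
  expect_true(all(abs(chk$rate - chk$expected) < chk$tol))
})

test_that("frailty induces positive code-level rate correlation; none without", {
  r_null <- replicate_rates(null_effect_config(n_codes = 2000,
                                               pop_log_mean = log(8000),
                                               pop_log_sd = 0.3), 41)
  wide <- data.table::dcast(r_null$rates, geo_code ~ condition,
                            value.var = "crude")
  expect_lt(abs(cor(wide$obesity, wide$depression)), 0.05)

  rs <- vapply(1:15, function(i) {
    r <- replicate_rates(null_effect_config(n_codes = 300, frailty_sd = 0.5), 100 + i)
    w <- data.table::dcast(r$rates, geo_code ~ condition, value.var = "crude")
    cor(w$obesity, w$depression, use = "complete.obs")
  }, numeric(1))
  expect_gt(mean(rs), 0.2)  # one-sided: decisively positive
})

test_that("generate_stays rejects mismatched code universes", {
  cfg <- sim_config(n_codes = 20, seed = 2)
  tabs <- generate_areal_tables(cfg)
  expect_error(generate_stays(cfg, tabs$census[geo_code != "G00001"],
                              tabs$socio),
               "code sets differ")
  socio_naked <- data.table::copy(tabs$socio)
  data.table::setattr(socio_naked, "latent", NULL)
  expect_error(generate_stays(cfg, tabs$census, socio_naked), "latent")
})
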