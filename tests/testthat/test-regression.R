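rates_from_values <- function(ob, de = NULL) {
  n <- length(ob)
  out <- data.table::data.table(geo_code = sprintf("R%03d", 1:n),
                                condition = "obesity", cases = 1L,
                                crude = ob, standardized = ob)
  if (!is.null(de))
    out <- rbind(out, data.table::data.table(geo_code = sprintf("R%03d", 1:n),
                                             condition = "depression",
                                             cases = 1L, crude = de,
                                             standardized = de))
  out
}

test_that("tertile assignment follows the order-statistic oracle", {
  ta <- assign_tertiles(rates_from_values(1:9), "obesity")
  tab <- ta$table[order(geo_code)]
  expect_equal(as.character(tab$tertile),
               rep(c("low", "mid", "high"), each = 3))
  expect_true(ta$cuts[1] <= ta$cuts[2])
  # n/3 +- 1 codes per tertile for distinct values
  set.seed(4)
  vals <- sample(seq(100, 2000, length.out = 100))
  ta2 <- assign_tertiles(rates_from_values(vals), "obesity")
  counts <- table(ta2$table$tertile)
  expect_true(all(abs(counts - 100 / 3) <= 1))
  # ties at a cut go downward: rate == t1 is low
  expect_true(all(ta$table[rate == ta$cuts[1]]$tertile == "low"))
})

test_that("degenerate tertiles are rejected", {
  expect_error(assign_tertiles(rates_from_values(rep(5, 10)), "obesity"),
               "distinct")
  expect_error(assign_tertiles(rates_from_values(c(1, 2)), "obesity"),
               "at least 3")
})

test_that("build_design produces the published dummy structure", {
  set.seed(9)
  n <- 60
  ob <- runif(n, 500, 2000); de <- runif(n, 100, 800)
  rates <- rates_from_values(ob, de)
  depr <- data.table::data.table(geo_code = sprintf("R%03d", 1:n),
                                 level = rep(1:5, length.out = n))
  socio <- data.table::data.table(geo_code = sprintf("R%03d", 1:n),
                                  typology = rep(typology_levels(),
                                                 length.out = n))
  to <- assign_tertiles(rates, "obesity")
  td <- assign_tertiles(rates, "depression")
  des <- build_design(to, td, depr, socio)
  expect_equal(dim(des$X), c(n, 10L))
  expect_equal(colnames(des$X)[1], "(Intercept)")
  # dummy columns sum to the count of codes at each level (cross-tab oracle)
  expect_equal(sum(des$X[, "depriv_5"]), sum(depr$level == 5))
  expect_equal(sum(des$X[, "typ_rural"]), sum(socio$typology == "rural"))
  expect_equal(sum(des$X[, "other_high"]),
               sum(td$table$tertile == "high"))
  expect_equal(sum(des$y), sum(to$table$tertile == "high"))
  # all-reference code: intercept-only row
  ref_rows <- des$X[depr$level == 2 & socio$typology == "major_urban" &
                      as.character(td$table$tertile) == "mid", , drop = FALSE]
  if (nrow(ref_rows)) expect_true(all(ref_rows[, -1] == 0))
  expect_error(build_design(to, td, depr[1:10], socio), "missing")
})

test_that("one binary covariate: fitted OR equals the cross-product ratio", {
  tab <- c(a = 37, b = 21, c = 15, d = 44)  # (x=1,y=1), (x=1,y=0), (x=0,y=1), (x=0,y=0)
  x <- rep(c(1, 1, 0, 0), tab)
  y <- rep(c(1, 0, 1, 0), tab)
  fit <- fit_logistic(cbind(1, x = x), y)
  expect_equal(unname(exp(fit$coefficients["x"])),
               (tab["a"] * tab["d"]) / (tab["b"] * tab["c"]),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("deviance never exceeds the null deviance (random fixtures)", {
  set.seed(100)
  for (i in 1:25) {
    n <- sample(40:120, 1)
    X <- cbind(1, matrix(rnorm(n * 3), n, 3))
    y <- rbinom(n, 1, plogis(X %*% c(-0.2, 0.5, 0, -0.7)))
    if (sum(y) %in% c(0, n)) next
    fit <- fit_logistic(X, y)
    expect_lte(fit$deviance, fit$null_deviance + 1e-8)
    # intercept score equation: fitted probabilities average to prevalence
    expect_equal(mean(fit$fitted), mean(y), tolerance = 1e-8)
  }
})

test_that("separation is detected and reported", {
  x <- rep(c(0, 1), each = 20)
  expect_error(fit_logistic(cbind(1, x = x), x), "separation")
  # rank deficiency is a distinct error
  X <- cbind(1, x, x)
  y <- rbinom(40, 1, 0.5)
  expect_error(fit_logistic(X, y), "rank deficient")
})

test_that("null covariates stay near zero at scale", {
  set.seed(123)
  hits <- vapply(1:30, function(i) {
    n <- 5000
    X <- cbind(1, d1 = rbinom(n, 1, 0.5))
    y <- rbinom(n, 1, 0.5)
    fit <- fit_logistic(X, y)
    all(abs(fit$coefficients[-1]) < 0.1)
  }, logical(1))
  expect_gte(mean(hits), 0.85)  # asymptotic null: ~92-95% of runs
})

test_that("Wald inference matches an independent reference implementation", {
  set.seed(11)
  n <- 400
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * X[, "x1"] - 0.6 * X[, "x2"]))
  fit <- fit_logistic(X, y)
  inf <- wald_inference(fit)
  ref <- glm(y ~ x1 + x2, family = binomial(),
             data = data.frame(y = y, x1 = X[, "x1"], x2 = X[, "x2"]),
             control = glm.control(epsilon = 1e-12))
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(inf$se, unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  # CI covers the point estimate; null coefficient closed form
  expect_true(all(inf$ci_low <= inf$or & inf$or <= inf$ci_high))
  z <- qnorm(0.975)
  expect_equal(inf$ci_low, inf$or * exp(-z * inf$se), tolerance = 1e-12)
})

test_that("relabeling y to 1 - y negates every coefficient", {
  set.seed(12)
  n <- 300
  X <- cbind(1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(0.3 + 0.5 * X[, 2]))
  f1 <- fit_logistic(X, y)
  f2 <- fit_logistic(X, 1 - y)
  expect_equal(f1$coefficients, -f2$coefficients, tolerance = 1e-7)
})

test_that("run_bidirectional recovers generator effect directions", {
  # strong deprivation gradient for obesity in the generator
  cfg <- sim_config(n_codes = 1200, seed = 19, frailty_sd = 0,
                    duplicate_rate = 0, under18_rate = 0, distractor_rate = 0)
  tabs <- generate_areal_tables(cfg)
  st <- generate_stays(cfg, tabs$census, tabs$socio)
  sel <- select_cases(st$stays)
  rates <- areal_rates(sel, tabs$census)
  depr <- build_deprivation(tabs$socio)
  res <- run_bidirectional(rates, depr, tabs$socio)
  for (m in res) {
    expect_s3_class(m, "eco_regression_result")
    expect_equal(nrow(m$table), 12L)
    expect_equal(m$table[reference_flag == TRUE]$OR, rep(1, 3))
  }
  t2 <- res$obesity$table
  or5 <- t2[level == "Most deprived"]$OR
  or1 <- t2[level == "Most advantaged"]$OR
  expect_gt(or5, or1)  # sign recovery of the deprivation gradient
})
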