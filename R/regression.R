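# Bidirectional ecological logistic regression.
#
# Each geographic code is one observation. The outcome is membership in the
# top tertile of one condition's standardized prevalence; predictors are the
# other condition's tertile (reference: mid), the 5-level deprivation index
# (reference: level 2, national average) and the urban typology (reference:
# major urban centers). Coefficients are maximized in-house by iteratively
# reweighted least squares; inference is Wald, from the inverse observed
# information at the optimum. No population weighting and no spatial
# correction of standard errors (the unit of analysis is the code).

#' Assign codes to prevalence tertiles
#'
#' Cut points are the empirical 1/3 and 2/3 quantiles (type-7 linear
#' interpolation) over codes with non-missing standardized rates, unweighted.
#' A code is `low` iff rate <= t1, `high` iff rate > t2, `mid` otherwise
#' (ties at a cut go downward).
#'
#' @param rates Long table from [areal_rates()].
#' @param condition `"obesity"` or `"depression"`.
#' @return Object of class `tertile_assignment`: list with `table`
#'   (`geo_code`, `rate`, `tertile` factor low/mid/high), `cuts` `(t1, t2)`,
#'   `condition`.
#' @export
assign_tertiles <- function(rates, condition) {
  cond <- condition
  r <- data.table::as.data.table(rates)[condition == cond & !is.na(standardized)]
  if (nrow(r) < 3L) stop("need at least 3 codes with rates", call. = FALSE)
  if (length(unique(r$standardized)) < 3L)
    stop("fewer than 3 distinct rate values: tertiles degenerate", call. = FALSE)
  cuts <- unname(quantile(r$standardized, c(1, 2) / 3, type = 7))
  tert <- ifelse(r$standardized <= cuts[1], "low",
                 ifelse(r$standardized > cuts[2], "high", "mid"))
  structure(list(
    table = data.table::data.table(
      geo_code = r$geo_code, rate = r$standardized,
      tertile = factor(tert, levels = c("low", "mid", "high"))),
    cuts = cuts, condition = cond),
    class = "tertile_assignment")
}

#' Build the design matrix and outcome for one ecological model
#'
#' @param tertiles_outcome Tertile assignment of the outcome condition; the
#'   binary outcome is membership in its high tertile.
#' @param tertiles_other Tertile assignment of the predictor condition; enters
#'   as dummies for low and high (reference: mid).
#' @param deprivation [build_deprivation()] output; dummies for levels 1, 3,
#'   4, 5 (reference: level 2).
#' @param socio Areal socio-economic table (for `typology`); dummies for
#'   suburbs, small/mid centers and rural (reference: major urban centers).
#' @return List: `X` (n x 10 matrix with intercept), `y` (0/1), `geo_code`.
#' @export
build_design <- function(tertiles_outcome, tertiles_other, deprivation, socio) {
  socio <- data.table::as.data.table(socio)
  d <- merge(tertiles_outcome$table[, .(geo_code, y_tert = tertile)],
             tertiles_other$table[, .(geo_code, o_tert = tertile)],
             by = "geo_code")
  d <- merge(d, deprivation[, .(geo_code, level)], by = "geo_code")
  d <- merge(d, socio[, .(geo_code, typology)], by = "geo_code")
  if (nrow(d) < nrow(tertiles_outcome$table))
    stop("missing covariates for some codes", call. = FALSE)
  if (anyNA(d)) stop("missing covariate values", call. = FALSE)
  X <- cbind(
    `(Intercept)` = 1,
    other_low = as.numeric(d$o_tert == "low"),
    other_high = as.numeric(d$o_tert == "high"),
    depriv_1 = as.numeric(d$level == 1L),
    depriv_3 = as.numeric(d$level == 3L),
    depriv_4 = as.numeric(d$level == 4L),
    depriv_5 = as.numeric(d$level == 5L),
    typ_suburbs = as.numeric(d$typology == "suburbs"),
    typ_small_mid = as.numeric(d$typology == "small_mid"),
    typ_rural = as.numeric(d$typology == "rural")
  )
  list(X = X, y = as.numeric(d$y_tert == "high"), geo_code = d$geo_code)
}

bernoulli_loglik <- function(y, eta) {
  sum(y * eta - log1p(exp(eta)))
}

#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximizes the Bernoulli log-likelihood by Fisher scoring (equivalently
#' IRLS), with step halving, to a gradient max-norm below `tol` or `max_iter`
#' iterations. Rank deficiency of `X` and (quasi-)complete separation
#' (diverging coefficients) are reported as distinct errors rather than
#' returned silently.
#'
#' @param X Numeric design matrix of full column rank (include the intercept).
#' @param y Binary 0/1 outcome vector.
#' @param max_iter Maximum iterations (default 100).
#' @param tol Convergence tolerance on the score max-norm (default 1e-8).
#' @return Object of class `eco_logistic_fit`: `coefficients`, `vcov`
#'   (inverse observed information), `loglik`, `deviance`, `null_deviance`,
#'   `fitted`, `converged`, `iterations`, `n`.
#' @export
fit_logistic <- function(X, y, max_iter = 100L, tol = 1e-8) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  p <- ncol(X)
  beta <- numeric(p)
  ll <- bernoulli_loglik(y, drop(X %*% beta))
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    w <- mu * (1 - mu)
    info <- crossprod(X * w, X)
    step <- tryCatch(solve(info, score), error = function(e)
      stop("singular information matrix (separation or collinearity)",
           call. = FALSE))
    # step halving to guarantee likelihood ascent
    new_beta <- beta + step
    new_ll <- bernoulli_loglik(y, drop(X %*% new_beta))
    h <- 0
    while (new_ll < ll - 1e-12 && h < 30) {
      step <- step / 2
      new_beta <- beta + step
      new_ll <- bernoulli_loglik(y, drop(X %*% new_beta))
      h <- h + 1
    }
    beta <- new_beta
    ll <- new_ll
    if (max(abs(beta)) > 25)
      stop("complete or quasi-complete separation detected ",
           "(coefficients diverging)", call. = FALSE)
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  if (!converged) {
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) < tol) converged <- TRUE
    else warning("IRLS did not converge in ", max_iter, " iterations",
                 call. = FALSE)
  }
  w <- mu * (1 - mu)
  info <- crossprod(X * w, X)
  vcov <- tryCatch(solve(info), error = function(e)
    stop("singular observed information at the optimum", call. = FALSE))
  pbar <- mean(y)
  null_ll <- if (pbar %in% c(0, 1)) 0 else
    sum(y * log(pbar) + (1 - y) * log(1 - pbar))
  structure(list(
    coefficients = setNames(drop(beta), colnames(X)),
    vcov = vcov, loglik = ll, deviance = -2 * ll,
    null_deviance = -2 * null_ll, fitted = mu,
    converged = converged, iterations = it, n = length(y)
  ), class = "eco_logistic_fit")
}

#' @export
print.eco_logistic_fit <- function(x, ...) {
  cat("<eco_logistic_fit> n =", x$n, " deviance =", round(x$deviance, 2),
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Wald inference for a fitted logistic model
#'
#' Standard errors from the inverse observed information at the optimum;
#' confidence interval `exp(beta +/- z * SE)`; two-sided normal p-value for
#' `beta = 0`.
#'
#' @param fit An `eco_logistic_fit`.
#' @param level Confidence level (default 0.95).
#' @return data.table per coefficient: `term`, `estimate`, `se`, `or`,
#'   `ci_low`, `ci_high`, `p`.
#' @export
wald_inference <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "eco_logistic_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  se <- sqrt(diag(fit$vcov))
  z <- qnorm(1 - (1 - level) / 2)
  b <- fit$coefficients
  data.table::data.table(
    term = names(b), estimate = unname(b), se = unname(se),
    or = exp(unname(b)),
    ci_low = exp(unname(b) - z * se), ci_high = exp(unname(b) + z * se),
    p = 2 * pnorm(-abs(unname(b) / se))
  )
}

# Presentation rows in the published-table layout, including reference rows.
format_eco_table <- function(inf, other_condition, cuts_other) {
  row <- function(predictor, label, tname = NA, reference = FALSE) {
    if (reference)
      data.table::data.table(predictor = predictor, level = label, OR = 1,
                             ci_low = NA_real_, ci_high = NA_real_,
                             p = NA_real_, reference_flag = TRUE)
    else {
      r <- inf[match(tname, inf$term)]
      data.table::data.table(predictor = predictor, level = label, OR = r$or,
                             ci_low = r$ci_low, ci_high = r$ci_high, p = r$p,
                             reference_flag = FALSE)
    }
  }
  pred <- paste0("Prevalence of ", other_condition, " (tertiles)")
  lab_low <- sprintf("%s - (0-%.0f)", other_condition, cuts_other[1])
  lab_high <- sprintf("%s + (> %.0f)", other_condition, cuts_other[2])
  data.table::rbindlist(list(
    row(pred, lab_low, "other_low"),
    row(pred, paste(other_condition, "="), reference = TRUE),
    row(pred, lab_high, "other_high"),
    row("Deprivation index", "Most advantaged", "depriv_1"),
    row("Deprivation index", "National average", reference = TRUE),
    row("Deprivation index", "Material deprivation", "depriv_3"),
    row("Deprivation index", "Social deprivation", "depriv_4"),
    row("Deprivation index", "Most deprived", "depriv_5"),
    row("Urban/Rural typology", "Major urban centers", reference = TRUE),
    row("Urban/Rural typology", "Suburbs of major centers", "typ_suburbs"),
    row("Urban/Rural typology", "Small and mid-sized centers", "typ_small_mid"),
    row("Urban/Rural typology", "Rural areas", "typ_rural")
  ))
}

#' Fit both ecological models (each condition's high tertile as outcome)
#'
#' Model A: outcome = obesity high tertile, predictors = depression tertile +
#' deprivation + typology. Model B: the mirror, with depression as outcome.
#'
#' @param rates Long table from [areal_rates()].
#' @param deprivation [build_deprivation()] output.
#' @param socio Areal socio-economic table.
#' @param level Confidence level for Wald intervals.
#' @return Named list (`obesity`, `depression`) of `eco_regression_result`
#'   objects, each holding `outcome`, `fit`, `inference`, `table` (published
#'   layout with reference rows), `tertiles` (outcome and predictor cuts),
#'   `n`.
#' @export
run_bidirectional <- function(rates, deprivation, socio, level = 0.95) {
  terts <- lapply(setNames(conditions(), conditions()),
                  function(cond) assign_tertiles(rates, cond))
  one <- function(outcome) {
    other <- setdiff(conditions(), outcome)
    des <- build_design(terts[[outcome]], terts[[other]], deprivation, socio)
    fit <- fit_logistic(des$X, des$y)
    inf <- wald_inference(fit, level)
    structure(list(
      outcome = outcome, fit = fit, inference = inf,
      table = format_eco_table(inf, other, terts[[other]]$cuts),
      tertiles = list(outcome = terts[[outcome]]$cuts,
                      other = terts[[other]]$cuts),
      n = fit$n
    ), class = "eco_regression_result")
  }
  list(obesity = one("obesity"), depression = one("depression"))
}

#' @export
print.eco_regression_result <- function(x, ...) {
  cat("<eco_regression_result> outcome: high tertile of", x$outcome,
      "(n =", x$n, "codes)\n")
  print(x$table, digits = 3)
  invisible(x)
}
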