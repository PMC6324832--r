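# Synthetic-data generator. Emulates the structure of national hospital
# discharge data aggregated over areal codes: census strata, socio-economic
# indicator shares driven by correlated latent deprivation scores, and
# stay-level records whose condition risks depend on age, sex, deprivation
# level, urban typology, and a shared code-level frailty u_g that induces
# areal co-prevalence of the two conditions.

# Exact multinomial split of each code's total population over strata,
# vectorized across codes via sequential conditional binomials.
split_multinomial <- function(totals, shares) {
  n <- length(totals)
  k <- length(shares)
  out <- matrix(0L, nrow = n, ncol = k)
  remaining <- as.integer(totals)
  rem_share <- rev(cumsum(rev(shares)))
  for (j in seq_len(k - 1L)) {
    p <- if (rem_share[j] > 0) min(1, shares[j] / rem_share[j]) else 0
    draw <- rbinom(n, remaining, p)
    out[, j] <- draw
    remaining <- remaining - draw
  }
  out[, k] <- remaining
  out
}

#' Generate areal census and socio-economic tables
#'
#' Draws each code's total adult population from a log-normal, splits it
#' exactly over the age-sex strata by multinomial sampling, and derives the
#' five socio-economic indicator shares from a pair of latent standard-normal
#' deprivation scores (correlation `socio_corr`) through fixed monotone
#' logistic links with small indicator-specific noise. The urban typology is
#' assigned by population rank (largest quartile = major urban centers, then
#' suburbs, small/mid-sized centers, rural areas).
#'
#' The returned socio table carries the latent scores and the true deprivation
#' level (classes cut at +/-1 on the latent scale, crossed to 5 levels) as a
#' `"latent"` attribute, used by [generate_stays()] and by recovery tests.
#'
#' @param config A [sim_config()].
#' @return List with elements `census` (one row per code x age band x sex:
#'   `geo_code`, `age_band`, `sex`, `population`) and `socio` (one row per
#'   code: indicator shares in `[0,1]` plus `typology`).
#' @export
generate_areal_tables <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_codes
  codes <- sprintf("G%05d", seq_len(n))

  tot <- pmax(1L, as.integer(round(exp(
    rnorm(n, config$pop_log_mean, config$pop_log_sd)))))

  strata <- config$age_sex_structure
  pops <- split_multinomial(tot, strata$share)
  census <- data.table::data.table(
    geo_code = rep(codes, times = nrow(strata)),
    age_band = rep(strata$age_band, each = n),
    sex = rep(strata$sex, each = n),
    population = as.integer(pops)
  )
  data.table::setorder(census, geo_code, age_band, sex)

  # latent deprivation scores: bivariate standard normal, corr = socio_corr
  rho <- config$socio_corr
  z_material <- rnorm(n)
  z_social <- rho * z_material + sqrt(1 - rho^2) * rnorm(n)

  noisy <- function(z) z + 0.3 * rnorm(n)
  socio <- data.table::data.table(
    geo_code = codes,
    unemployment = plogis(-2.2 + 0.35 * noisy(z_social)),
    blue_collar  = plogis(-1.1 + 0.30 * noisy(z_social)),
    low_diploma  = plogis(-1.0 + 0.30 * noisy(z_social)),
    immigrant    = plogis(-2.5 + 0.50 * noisy(z_social)),
    non_taxable  = plogis(-0.3 + 0.40 * noisy(z_material))
  )
  qt <- ceiling(4 * rank(-tot, ties.method = "first") / n)
  socio[, typology := typology_levels()[qt]]

  true_level <- cross_levels(classify_score(z_material), classify_score(z_social))
  data.table::setattr(socio, "latent", data.table::data.table(
    geo_code = codes, z_social = z_social, z_material = z_material,
    true_level = true_level))
  list(census = census, socio = socio)
}

# diagnosis code pools used when fabricating stay records
.codes_obesity  <- c("E66.0", "E66.9", "E66.8", "E660", "E66.2")
.codes_depress  <- c("F32.1", "F32.9", "F33.1", "F33.2", "F320")
.codes_selfharm <- c("X60", "X64", "X70", "X78", "X84")
.codes_somatic  <- c("I10", "E11.9", "J44.1", "M16.9")
.codes_injury   <- c("T39.0", "S61.9", "T42.4")

#' Generate stay-level hospital records with known ground truth
#'
#' For every stratum of every code, case counts for each condition are drawn
#' binomially with individual log-odds
#' `baseline(age band, sex) + beta_deprivation(level) + beta_typology +
#' lambda_condition * u_g`, where `u_g ~ N(0, frailty_sd)` is shared between
#' the two conditions. Each case becomes `1 + Poisson(duplicate_rate)` stay
#' records sharing one patient id, coded through realistic ascertainment
#' pathways (obesity: E66 as main or associated diagnosis in acute care;
#' depression: main-diagnosis F32/F33 in acute care, self-harm plus F32/F33 as
#' associated diagnoses in the same acute-care stay, or any-role F32/F33 in
#' psychiatric care, in configured proportions). Additional under-18 patients
#' and non-qualifying distractor stays are injected to exercise the selection
#' rules; neither is counted in the ground truth.
#'
#' @param config A [sim_config()].
#' @param census,socio Tables from [generate_areal_tables()] (the socio table
#'   must retain its latent attribute).
#' @return List with `stays` (long table: `stay_id`, `patient_id`, `source`,
#'   `geo_code`, `age`, `sex`, `diag_code`, `diag_role`; one row per diagnosis)
#'   and `truth` (a `ground_truth` list: per-code true case counts, true
#'   covariate odds ratios, frailty parameters, totals).
#' @export
generate_stays <- function(config, census, socio) {
  validate_sim_config(config)
  latent <- attr(socio, "latent", exact = TRUE)
  if (is.null(latent))
    stop("socio must come from generate_areal_tables() (latent attribute required)",
         call. = FALSE)
  if (!setequal(unique(census$geo_code), socio$geo_code))
    stop("census and socio geographic code sets differ", call. = FALSE)
  set.seed(derive_seed(config$seed, 2L))

  codes <- socio$geo_code
  n <- length(codes)
  u <- rnorm(n, 0, config$frailty_sd)
  names(u) <- codes

  strat <- data.table::copy(census)
  strat <- merge(strat, socio[, .(geo_code, typology)], by = "geo_code")
  strat <- merge(strat, latent[, .(geo_code, true_level)], by = "geo_code")
  base <- config$baseline_logits
  data.table::setkey(base, age_band, sex)

  typ_idx <- match(strat$typology, typology_levels())
  base_rows <- base[strat[, .(age_band, sex)]]

  draw_cases <- function(cond) {
    logit <- base_rows[[cond]] +
      config$beta_deprivation[[cond]][strat$true_level] +
      config$beta_typology[[cond]][typ_idx] +
      config$frailty_loadings[[cond]] * u[strat$geo_code]
    rbinom(nrow(strat), strat$population, plogis(logit))
  }
  n_ob <- draw_cases("obesity")
  n_de <- draw_cases("depression")

  expand_cases <- function(counts) {
    idx <- rep(seq_len(nrow(strat)), counts)
    dt <- strat[idx, .(geo_code, age_band, sex)]
    if (nrow(dt)) {
      rng <- band_age_range(as.character(dt$age_band))
      dt[, age := as.integer(rng[, "lo"] +
                               floor(runif(.N) * (rng[, "hi"] - rng[, "lo"] + 1)))]
    } else dt[, age := integer(0)]
    dt[, age_band := NULL]
    dt
  }
  ob_cases <- expand_cases(n_ob)
  de_cases <- expand_cases(n_de)
  n_cases <- nrow(ob_cases) + nrow(de_cases)
  ob_cases[, patient_id := seq_len(.N)]
  de_cases[, patient_id := nrow(ob_cases) + seq_len(.N)]

  # one diagnosis-pattern block per case (1-3 rows), replicated per stay
  pattern_obesity <- function(dt) {
    if (!nrow(dt)) return(NULL)
    main_role <- runif(nrow(dt)) < 0.6
    code <- sample(.codes_obesity, nrow(dt), replace = TRUE)
    own <- dt[, .(patient_id, source = "MCO", diag_code = code,
                  diag_role = ifelse(main_role, "main", "associated"))]
    filler <- dt[!main_role][, .(patient_id, source = "MCO",
                                 diag_code = sample(.codes_somatic, .N, replace = TRUE),
                                 diag_role = "main")]
    data.table::rbindlist(list(own, filler))
  }
  pattern_depression <- function(dt) {
    if (!nrow(dt)) return(NULL)
    pw <- sample(names(config$depression_pathways), nrow(dt), replace = TRUE,
                 prob = config$depression_pathways)
    f3 <- sample(.codes_depress, nrow(dt), replace = TRUE)
    parts <- list()
    i <- pw == "mco_main"
    parts$main <- dt[i][, .(patient_id, source = "MCO", diag_code = f3[i],
                            diag_role = "main")]
    i <- pw == "mco_selfharm"
    if (any(i)) {
      sub <- dt[i]
      parts$sh <- data.table::rbindlist(list(
        sub[, .(patient_id, source = "MCO",
                diag_code = sample(.codes_injury, .N, replace = TRUE),
                diag_role = "main")],
        sub[, .(patient_id, source = "MCO",
                diag_code = sample(.codes_selfharm, .N, replace = TRUE),
                diag_role = "associated")],
        sub[, .(patient_id, source = "MCO", diag_code = f3[i],
                diag_role = "associated")]
      ))
    }
    i <- pw == "rimp"
    if (any(i)) {
      sub <- dt[i]
      main_role <- runif(nrow(sub)) < 0.7
      parts$rimp <- sub[, .(patient_id, source = "RIMP", diag_code = f3[i],
                            diag_role = ifelse(main_role, "main", "associated"))]
    }
    data.table::rbindlist(parts)
  }

  patients <- data.table::rbindlist(list(ob_cases, de_cases))
  patterns <- data.table::rbindlist(list(pattern_obesity(ob_cases),
                                         pattern_depression(de_cases)))

  # injected under-18 patients with otherwise qualifying codes
  n_u18 <- round(config$under18_rate * n_cases)
  if (n_u18 > 0) {
    u18 <- data.table::data.table(
      geo_code = sample(codes, n_u18, replace = TRUE),
      sex = sample(c("F", "M"), n_u18, replace = TRUE),
      age = sample(10:17, n_u18, replace = TRUE),
      patient_id = n_cases + seq_len(n_u18)
    )
    half <- runif(n_u18) < 0.5
    patterns <- data.table::rbindlist(list(
      patterns,
      u18[half][, .(patient_id, source = "MCO",
                    diag_code = sample(.codes_obesity, .N, replace = TRUE),
                    diag_role = "main")],
      u18[!half][, .(patient_id, source = "MCO",
                     diag_code = sample(.codes_depress, .N, replace = TRUE),
                     diag_role = "main")]
    ))
    patients <- data.table::rbindlist(list(patients, u18), use.names = TRUE)
  }

  # distractor patients: stays that must NOT qualify under the selection rules
  n_dis <- round(config$distractor_rate * n_cases)
  if (n_dis > 0) {
    dis <- data.table::data.table(
      geo_code = sample(codes, n_dis, replace = TRUE),
      sex = sample(c("F", "M"), n_dis, replace = TRUE),
      age = sample(18:90, n_dis, replace = TRUE),
      patient_id = n_cases + n_u18 + seq_len(n_dis),
      kind = rep_len(c("assoc_f32", "diabetes", "anxiety", "selfharm_only",
                       "psychosis"), n_dis)
    )
    mk <- function(sub, source, main_code, assoc_code = NULL) {
      if (!nrow(sub)) return(NULL)
      out <- sub[, .(patient_id, source = source, diag_code = main_code,
                     diag_role = "main")]
      if (!is.null(assoc_code))
        out <- data.table::rbindlist(list(
          out, sub[, .(patient_id, source = source, diag_code = assoc_code,
                       diag_role = "associated")]))
      out
    }
    patterns <- data.table::rbindlist(list(
      patterns,
      mk(dis[kind == "assoc_f32"], "MCO", "I10", "F32.9"),
      mk(dis[kind == "diabetes"], "MCO", "E11.9"),
      mk(dis[kind == "anxiety"], "RIMP", "F41.9"),
      mk(dis[kind == "selfharm_only"], "MCO", "S61.9", "X70"),
      mk(dis[kind == "psychosis"], "MCO", "F20.0")
    ))
    patients <- data.table::rbindlist(list(patients, dis[, !"kind"]),
                                      use.names = TRUE)
  }

  # stay expansion: each patient-pattern gets 1 + Poisson(duplicate_rate) stays
  n_stays <- 1L + rpois(nrow(patients), config$duplicate_rate)
  stay_tbl <- data.table::data.table(
    patient_id = rep(patients$patient_id, n_stays))
  stay_tbl <- stay_tbl[sample(.N)]          # shuffle stay order
  stay_tbl[, stay_id := .I]
  rows <- merge(stay_tbl, patterns, by = "patient_id", allow.cartesian = TRUE)
  rows <- merge(rows, patients[, .(patient_id, geo_code, age, sex)],
                by = "patient_id")
  stays <- rows[, .(stay_id, patient_id, source, geo_code, age, sex,
                    diag_code, diag_role)]
  data.table::setorder(stays, stay_id)

  cases_by_code <- data.table::rbindlist(list(
    ob_cases[, .(cases = .N), by = geo_code][, condition := "obesity"],
    de_cases[, .(cases = .N), by = geo_code][, condition := "depression"]
  ))
  all_codes <- data.table::CJ(geo_code = codes, condition = conditions())
  cases_by_code <- merge(all_codes, cases_by_code,
                         by = c("geo_code", "condition"), all.x = TRUE)
  cases_by_code[is.na(cases), cases := 0L]

  truth <- structure(list(
    n_cases = c(obesity = nrow(ob_cases), depression = nrow(de_cases)),
    cases_by_code = cases_by_code,
    or_deprivation = lapply(config$beta_deprivation, exp),
    or_typology = lapply(config$beta_typology, exp),
    frailty_sd = config$frailty_sd,
    frailty_loadings = config$frailty_loadings,
    n_under18 = n_u18, n_distractors = n_dis,
    cross_or = NA_real_
  ), class = "ground_truth")

  list(stays = stays, truth = truth)
}

#' Write a complete synthetic dataset to disk
#'
#' Runs both generators and writes `census.csv`, `socio.csv`, `stays.csv` and
#' `truth.json` into `dir`. Output is byte-for-byte reproducible for a fixed
#' config (including its seed).
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the written file paths.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- generate_areal_tables(config)
  st <- generate_stays(config, tabs$census, tabs$socio)
  paths <- c(census = file.path(dir, "census.csv"),
             socio = file.path(dir, "socio.csv"),
             stays = file.path(dir, "stays.csv"),
             truth = file.path(dir, "truth.json"))
  data.table::fwrite(tabs$census, paths["census"])
  data.table::fwrite(tabs$socio, paths["socio"])
  data.table::fwrite(st$stays, paths["stays"])
  truth <- unclass(st$truth)
  truth$cases_by_code <- as.data.frame(truth$cases_by_code)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

# One simulated replicate -> fitted cross-condition high-vs-mid log-OR for the
# obesity-high outcome model. Used by calibration and recovery machinery.
replicate_cross_logor <- function(config, seed) {
  cfg <- config
  cfg$seed <- seed
  tabs <- generate_areal_tables(cfg)
  st <- generate_stays(cfg, tabs$census, tabs$socio)
  sel <- select_cases(st$stays)
  rates <- areal_rates(sel, tabs$census)
  depr <- build_deprivation(tabs$socio)
  res <- run_bidirectional(rates, depr, tabs$socio)
  c(obesity = unname(res$obesity$fit$coefficients["other_high"]),
    depression = unname(res$depression$fit$coefficients["other_high"]))
}

#' Calibrate the shared frailty to a target cross-condition odds ratio
#'
#' Finds, by Monte-Carlo simulation, the `frailty_sd` at which the ecological
#' regression's cross-condition odds ratio (high vs mid tertile of the other
#' condition, averaged over the two directions) attains `target_or` in
#' expectation under the given configuration. This is the generation-time
#' calibration used to give synthetic datasets a known code-level association
#' between the two conditions.
#'
#' The induced log odds ratio is very nearly linear in `frailty_sd^2` over
#' the relevant range, so the calibration fits that line on a coarse grid and
#' then applies one Newton correction step at the interpolated candidate.
#'
#' @param config A [sim_config()]; its `frailty_sd` is ignored.
#' @param target_or Target cross-condition odds ratio (> 1).
#' @param n_reps Simulated replicates per grid point.
#' @param grid Frailty SDs probed for the linear fit.
#' @param refine_reps Replicates for the Newton correction and the final
#'   evaluation.
#' @return List: `frailty_sd` (calibrated value), `achieved_log_or` (Monte
#'   Carlo mean at that value), `achieved_or`.
#' @export
calibrate_frailty <- function(config, target_or, n_reps = 12,
                              grid = c(0.06, 0.10, 0.14), refine_reps = 32) {
  stopifnot(target_or > 1)
  target <- log(target_or)
  eval_at <- function(sd, offset, reps) {
    cfg <- config
    cfg$frailty_sd <- sd
    mean(vapply(seq_len(reps), function(r) {
      mean(replicate_cross_logor(cfg, derive_seed(config$seed,
                                                  offset * 1000L + r)))
    }, numeric(1)))
  }
  means <- vapply(seq_along(grid), function(i) eval_at(grid[i], i, n_reps),
                  numeric(1))
  b <- stats::coef(stats::lm(means ~ I(grid^2)))
  cand <- sqrt(max((target - b[1]) / b[2], 1e-4))
  est <- eval_at(cand, 99L, refine_reps)
  sd_star <- sqrt(max(cand^2 + (target - est) / b[2], 1e-4))
  achieved <- eval_at(sd_star, 98L, refine_reps)
  list(frailty_sd = sd_star, achieved_log_or = achieved,
       achieved_or = exp(achieved))
}

#' Estimate the induced cross-condition odds ratio by simulation
#'
#' Monte-Carlo estimate (with standard error) of the ecological
#' cross-condition high-vs-mid log odds ratio induced by a configuration,
#' averaged over both regression directions.
#'
#' @param config A [sim_config()].
#' @param n_reps Number of simulated replicates.
#' @return List: `log_or` (mean), `se` (Monte Carlo standard error of the
#'   mean), `or`.
#' @export
estimate_cross_or <- function(config, n_reps = 20) {
  vals <- vapply(seq_len(n_reps), function(r) {
    mean(replicate_cross_logor(config, derive_seed(config$seed, 5000L + r)))
  }, numeric(1))
  list(log_or = mean(vals), se = sd(vals) / sqrt(n_reps),
       or = exp(mean(vals)))
}
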