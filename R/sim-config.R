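# Simulation configuration: the "stated world" every synthetic dataset is drawn
# from. Defaults emulate the scale and structure of a national hospital
# discharge system: thousands of areal codes with log-normal population sizes,
# an adult age-sex pyramid, hospital-treated prevalences around 0.5-1.5% with
# realistic age-sex profiles, deprivation and urbanicity effects on the
# individual log-odds, and a shared area-level frailty that induces areal
# co-prevalence of the two conditions.

#' Default adult age-sex population structure
#'
#' Stratum shares (summing to 1) over the 9 age bands crossed with sex,
#' approximating a Western European adult pyramid with a 51.2/48.8
#' female/male split applied uniformly across bands.
#'
#' @return data.table with columns `age_band`, `sex`, `share`.
#' @export
default_age_sex_structure <- function() {
  band_share <- c(`18-19` = 0.031, `20-29` = 0.148, `30-39` = 0.158,
                  `40-49` = 0.167, `50-59` = 0.167, `60-69` = 0.152,
                  `70-79` = 0.103, `80-89` = 0.058, `90+` = 0.016)
  out <- data.table::CJ(age_band = age_band_levels(), sex = c("F", "M"),
                        sorted = FALSE)
  out[, share := band_share[age_band] * ifelse(sex == "F", 0.512, 0.488)]
  out[]
}

#' Default per-stratum baseline log-odds of hospital-treated prevalence
#'
#' Anchored to published national age-sex prevalence profiles per 100,000
#' inhabitants: obesity rising with age and peaking in the 70-79 band
#' (2,847 for men, 2,432 for women), depression peaking at 1,165 for women
#' aged 50-59 and at 798 for men aged 90 and over.
#'
#' @return data.table with columns `age_band`, `sex`, `obesity`, `depression`
#'   (log-odds scale).
#' @export
default_baseline_logits <- function() {
  b <- age_band_levels()
  # per-100,000 rates, F then M, by band
  ob_f <- c(500, 800, 1100, 1400, 1700, 2100, 2432, 1800, 1000)
  ob_m <- c(300, 400,  600,  900, 1400, 2100, 2847, 2200, 1200)
  de_f <- c(400, 550,  750, 1000, 1165,  900,  800,  850,  900)
  de_m <- c(250, 300,  400,  500,  600,  550,  600,  700,  798)
  out <- data.table::data.table(
    age_band = rep(b, 2L),
    sex = rep(c("F", "M"), each = length(b)),
    obesity = qlogis(c(ob_f, ob_m) / 1e5),
    depression = qlogis(c(de_f, de_m) / 1e5)
  )
  out[]
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator. Defaults are the
#' package's stated world (see the methods vignette); override individual
#' arguments rather than editing the returned list.
#'
#' @param n_codes Number of geographic codes (areal units); must be >= 2.
#' @param pop_log_mean,pop_log_sd Log-normal parameters of each code's total
#'   adult population. Defaults give a median of ~1,200 inhabitants with
#'   heavy right tail (villages to large cities).
#' @param age_sex_structure data.table of stratum shares summing to 1
#'   (columns `age_band`, `sex`, `share`).
#' @param frailty_sd Standard deviation of the shared area-level random
#'   effect `u_g` (log-odds scale); 0 disables areal co-prevalence.
#' @param frailty_loadings Named numeric of length 2 (`obesity`,
#'   `depression`): per-condition loadings on `u_g`.
#' @param beta_deprivation Named list with per-condition numeric vectors of
#'   length 5: log-odds increments by deprivation level (level 2, the
#'   national average, is the reference at 0). Defaults are the log odds
#'   ratios of published ecological gradients for the two conditions.
#' @param beta_typology Named list with per-condition numeric vectors of
#'   length 4 in [typology_levels()] order (major urban centers reference).
#' @param baseline_logits data.table as [default_baseline_logits()].
#' @param socio_corr Correlation of the latent social and material
#'   deprivation scores across codes.
#' @param duplicate_rate Expected number of extra stays per case
#'   (Poisson); 0 yields exactly one stay per case and condition.
#' @param depression_pathways Named numeric summing to 1: proportions of
#'   depression cases ascertained through each coding pathway
#'   (`mco_main`, `mco_selfharm`, `rimp`).
#' @param under18_rate Fraction (of total cases) of additional under-18
#'   patients with qualifying-looking codes, injected to exercise the adult
#'   filter.
#' @param distractor_rate Fraction (of total cases) of additional patients
#'   whose stays carry non-qualifying code patterns (e.g. an associated
#'   F32 in an acute-care stay without a self-harm code).
#' @param seed Integer RNG seed; all generator sub-streams derive from it.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_codes = 500,
                       pop_log_mean = log(1200),
                       pop_log_sd = 1.0,
                       age_sex_structure = default_age_sex_structure(),
                       frailty_sd = 0.2,
                       frailty_loadings = c(obesity = 1, depression = 1),
                       beta_deprivation = list(
                         obesity    = log(c(0.444, 1, 1.484, 2.243, 3.583)),
                         depression = log(c(0.694, 1, 1.233, 1.157, 1.648))
                       ),
                       beta_typology = list(
                         obesity    = log(c(1, 1.594, 1.373, 1.492)),
                         depression = log(c(1, 0.765, 2.218, 1.281))
                       ),
                       baseline_logits = default_baseline_logits(),
                       socio_corr = 0.6,
                       duplicate_rate = 0.4,
                       depression_pathways = c(mco_main = 0.5,
                                               mco_selfharm = 0.1,
                                               rimp = 0.4),
                       under18_rate = 0.02,
                       distractor_rate = 0.1,
                       seed = 1L) {
  cfg <- list(
    n_codes = as.integer(n_codes), pop_log_mean = pop_log_mean,
    pop_log_sd = pop_log_sd,
    age_sex_structure = data.table::as.data.table(age_sex_structure),
    frailty_sd = frailty_sd, frailty_loadings = frailty_loadings,
    beta_deprivation = beta_deprivation, beta_typology = beta_typology,
    baseline_logits = data.table::as.data.table(baseline_logits),
    socio_corr = socio_corr, duplicate_rate = duplicate_rate,
    depression_pathways = depression_pathways,
    under18_rate = under18_rate, distractor_rate = distractor_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (is.na(cfg$n_codes) || cfg$n_codes < 2L)
    stop("n_codes must be at least 2", call. = FALSE)
  if (abs(sum(cfg$age_sex_structure$share) - 1) > 1e-9)
    stop("age_sex_structure shares must sum to 1 (within 1e-9)", call. = FALSE)
  if (any(cfg$age_sex_structure$share < 0))
    stop("age_sex_structure shares must be non-negative", call. = FALSE)
  if (cfg$frailty_sd < 0) stop("frailty_sd must be >= 0", call. = FALSE)
  if (cfg$duplicate_rate < 0) stop("duplicate_rate must be >= 0", call. = FALSE)
  if (cfg$pop_log_sd < 0) stop("pop_log_sd must be >= 0", call. = FALSE)
  if (abs(cfg$socio_corr) > 1) stop("socio_corr must lie in [-1, 1]", call. = FALSE)
  for (cond in conditions()) {
    if (length(cfg$beta_deprivation[[cond]]) != 5L)
      stop("beta_deprivation$", cond, " must have length 5", call. = FALSE)
    if (length(cfg$beta_typology[[cond]]) != 4L)
      stop("beta_typology$", cond, " must have length 4", call. = FALSE)
  }
  if (abs(sum(cfg$depression_pathways) - 1) > 1e-9)
    stop("depression_pathways must sum to 1", call. = FALSE)
  invisible(cfg)
}

# Deterministic sub-stream seeds derived from the single config seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% 2147483629)
}
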