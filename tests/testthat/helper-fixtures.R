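# Shared fixtures, built in code.

# Long-format stay row
stay_row <- function(stay_id, patient_id, source, geo_code, age, sex,
                     diag_code, diag_role) {
  data.table::data.table(stay_id = stay_id, patient_id = patient_id,
                         source = source, geo_code = geo_code, age = age,
                         sex = sex, diag_code = diag_code,
                         diag_role = diag_role)
}

# Hand-built 30-stay fixture covering every selection pathway, duplicate
# stays, an under-18 patient, conflicting geo codes, and distractor patterns.
# Annotations (the expected case sets) are attached as attributes.
selection_fixture <- function() {
  rows <- list(
    # P1: three qualifying obesity stays (main, associated, main) -> 1 member
    stay_row(1, "P1", "MCO", "A", 40, "F", "E66.0", "main"),
    stay_row(2, "P1", "MCO", "A", 40, "F", "I10", "main"),
    stay_row(2, "P1", "MCO", "A", 40, "F", "E660", "associated"),
    stay_row(3, "P1", "MCO", "A", 40, "F", "E66.8", "main"),
    # P2: MCO main F32 (+ exact duplicate stay)
    stay_row(4, "P2", "MCO", "A", 30, "M", "F32.1", "main"),
    stay_row(5, "P2", "MCO", "A", 30, "M", "F32.1", "main"),
    # P3: MCO self-harm pathway: associated X70 + associated F33
    stay_row(6, "P3", "MCO", "B", 50, "F", "T39.0", "main"),
    stay_row(6, "P3", "MCO", "B", 50, "F", "X70", "associated"),
    stay_row(6, "P3", "MCO", "B", 50, "F", "F33.2", "associated"),
    # P4: RIMP associated F33 (+ duplicate)
    stay_row(7, "P4", "RIMP", "B", 60, "M", "F41.9", "main"),
    stay_row(7, "P4", "RIMP", "B", 60, "M", "F33", "associated"),
    stay_row(8, "P4", "RIMP", "B", 60, "M", "F41.9", "main"),
    stay_row(8, "P4", "RIMP", "B", 60, "M", "F33", "associated"),
    # P5: RIMP main F32
    stay_row(9, "P5", "RIMP", "A", 45, "F", "F32.9", "main"),
    # P6: distractor - MCO associated F32 without self-harm
    stay_row(10, "P6", "MCO", "A", 55, "M", "I10", "main"),
    stay_row(10, "P6", "MCO", "A", 55, "M", "F32.9", "associated"),
    # P7: distractor - unrelated diagnosis
    stay_row(11, "P7", "MCO", "B", 35, "F", "E11.9", "main"),
    # P8: under-18 obesity stay -> excluded
    stay_row(12, "P8", "MCO", "A", 17, "M", "E66.9", "main"),
    # P9: obesity + associated F32 in MCO (depression must NOT fire)
    stay_row(13, "P9", "MCO", "B", 62, "F", "E66.1", "main"),
    stay_row(13, "P9", "MCO", "B", 62, "F", "F32.0", "associated"),
    # P10: one stay carrying both conditions
    stay_row(14, "P10", "MCO", "A", 48, "M", "F33.1", "main"),
    stay_row(14, "P10", "MCO", "A", 48, "M", "E66.9", "associated"),
    # P11: two stays, one per condition
    stay_row(15, "P11", "MCO", "B", 52, "F", "F32", "main"),
    stay_row(16, "P11", "MCO", "B", 52, "F", "E66", "main"),
    # P12: associated X85 + associated F32 (qualifies only under literal X8*)
    stay_row(17, "P12", "MCO", "A", 41, "M", "S61.9", "main"),
    stay_row(17, "P12", "MCO", "A", 41, "M", "X85", "associated"),
    stay_row(17, "P12", "MCO", "A", 41, "M", "F32.2", "associated"),
    # P13: conflicting geo codes across two obesity stays -> first wins
    stay_row(18, "P13", "MCO", "A", 70, "F", "E66.0", "main"),
    stay_row(19, "P13", "MCO", "B", 70, "F", "E66.0", "main"),
    # P14: RIMP dot-stripped code variant
    stay_row(20, "P14", "RIMP", "B", 29, "M", "F320", "main"),
    # P15: self-harm code alone (no F32/F33) -> nothing
    stay_row(21, "P15", "MCO", "A", 33, "F", "X70", "main"),
    # P16: MAIN self-harm + associated F33: associated-role rule must not fire
    stay_row(22, "P16", "MCO", "B", 44, "M", "X70", "main"),
    stay_row(22, "P16", "MCO", "B", 44, "M", "F33.0", "associated"),
    # P17: distractor - RIMP anxiety
    stay_row(23, "P17", "RIMP", "A", 38, "F", "F41.0", "main"),
    # P18: obesity as associated diagnosis only
    stay_row(24, "P18", "MCO", "A", 58, "M", "M16.9", "main"),
    stay_row(24, "P18", "MCO", "A", 58, "M", "E66.2", "associated"),
    # P19: psychotic disorder distractor in MCO
    stay_row(25, "P19", "MCO", "B", 47, "F", "F20.0", "main"),
    # extra duplicate stays to reach 30 stays
    stay_row(26, "P1", "MCO", "A", 40, "F", "E66.0", "main"),
    stay_row(27, "P5", "RIMP", "A", 45, "F", "F32.9", "main"),
    stay_row(28, "P6", "MCO", "A", 55, "M", "I10", "main"),
    stay_row(29, "P9", "MCO", "B", 62, "F", "E66.1", "main"),
    stay_row(30, "P14", "RIMP", "B", 29, "M", "F320", "main")
  )
  stays <- data.table::rbindlist(rows)
  attr(stays, "expect_obesity") <- sort(c("P1", "P9", "P10", "P11", "P13", "P18"))
  attr(stays, "expect_depression_x89") <-
    sort(c("P2", "P3", "P4", "P5", "P10", "P11", "P12", "P14"))
  attr(stays, "expect_depression_x84") <-
    sort(c("P2", "P3", "P4", "P5", "P10", "P11", "P14"))
  stays
}

# Small, fast configuration for Monte-Carlo property tests: covariate effects
# off so code-level association is driven by the frailty alone.
null_effect_config <- function(n_codes = 1000, frailty_sd = 0, seed = 1L, ...) {
  sim_config(
    n_codes = n_codes, frailty_sd = frailty_sd, seed = seed,
    duplicate_rate = 0, under18_rate = 0, distractor_rate = 0,
    beta_deprivation = list(obesity = rep(0, 5), depression = rep(0, 5)),
    beta_typology = list(obesity = rep(0, 4), depression = rep(0, 4)),
    ...
  )
}

# Generate one replicate and run the pipeline up to areal rates.
replicate_rates <- function(config, seed) {
  cfg <- config
  cfg$seed <- seed
  tabs <- generate_areal_tables(cfg)
  st <- generate_stays(cfg, tabs$census, tabs$socio)
  sel <- select_cases(st$stays)
  list(tabs = tabs, sel = sel, rates = areal_rates(sel, tabs$census))
}

# A simple case_set for standardization tests: ages/sex/codes as given.
make_case_set <- function(condition, geo_code, age, sex) {
  structure(list(
    condition = condition,
    members = data.table::data.table(
      patient_id = seq_along(age), geo_code = geo_code, age = age, sex = sex)),
    class = "case_set")
}
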