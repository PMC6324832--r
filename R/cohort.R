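# Case ascertainment from stay-level records.
#
# Selection rules (per stay):
#   obesity    : acute-care (MCO) stay with an E66 diagnosis in any role.
#   depression : acute-care stay with F32/F33 as MAIN diagnosis; OR an
#                acute-care stay carrying both a self-harm code (X6*/X7*/X8*)
#                and F32/F33 as ASSOCIATED diagnoses; OR a psychiatric (RIM-P)
#                stay with F32/F33 in any role.
# Patients are then deduplicated (one membership per condition regardless of
# stay count) and restricted to age >= 18.

normalize_icd <- function(code) {
  toupper(gsub(".", "", code, fixed = TRUE))
}

#' Match an ICD-10 code against a prefix pattern
#'
#' Codes are compared after uppercasing and stripping dots, so `"E66.0"` and
#' `"E660"` are equivalent. The pattern is a literal prefix; a single `*` is
#' allowed only as a trailing wildcard (and is redundant, since matching is by
#' prefix).
#'
#' @param code ICD-10 code (character vector).
#' @param pattern Literal prefix, optionally ending in `*`.
#' @return Logical vector: does each code start with the pattern?
#' @export
#' @examples
#' match_icd("E66.0", "E66")  # TRUE
#' match_icd("X70", "X7*")    # TRUE
match_icd <- function(code, pattern) {
  stopifnot(is.character(code), length(pattern) == 1L, nzchar(pattern))
  if (any(!nzchar(code))) stop("empty ICD code", call. = FALSE)
  stripped <- sub("\\*$", "", pattern)
  if (grepl("*", stripped, fixed = TRUE))
    stop("malformed pattern '", pattern,
         "': '*' is only allowed as a trailing wildcard", call. = FALSE)
  startsWith(normalize_icd(code), normalize_icd(stripped))
}

# Self-harm prefix set. The literal reading of the selection rule is prefixes
# X6/X7/X8 (i.e. X60-X89); ICD-10 intentional self-harm proper is X60-X84, so
# selfharm_upper_bound = "X84" restricts the X8 block accordingly.
is_selfharm_code <- function(norm_code, selfharm_upper_bound = c("X89", "X84")) {
  selfharm_upper_bound <- match.arg(selfharm_upper_bound)
  hit <- startsWith(norm_code, "X6") | startsWith(norm_code, "X7") |
    startsWith(norm_code, "X8")
  if (selfharm_upper_bound == "X84")
    hit <- hit & !(substr(norm_code, 1, 3) %in% c("X85", "X86", "X87", "X88", "X89"))
  hit
}

#' Classify stays into condition flags (vectorized)
#'
#' @param stays Long stay table: one row per diagnosis, columns `stay_id`,
#'   `patient_id`, `source` (`"MCO"` acute care / `"RIMP"` psychiatric),
#'   `geo_code`, `age`, `sex`, `diag_code`, `diag_role`
#'   (`"main"`/`"associated"`).
#' @param selfharm_upper_bound `"X89"` (literal X6*/X7*/X8* reading, default)
#'   or `"X84"` (strict intentional self-harm block).
#' @return data.table with one row per stay: `stay_id`, `patient_id`,
#'   `geo_code`, `age`, `sex`, and logical `obesity`, `depression` flags.
#'   Flags are independent; a stay may carry both.
#' @export
classify_stays <- function(stays, selfharm_upper_bound = "X89") {
  stays <- data.table::as.data.table(stays)
  norm <- normalize_icd(stays$diag_code)
  d <- stays[, .(stay_id, patient_id, source, geo_code, age, sex)]
  is_main <- stays$diag_role == "main"
  is_f3 <- startsWith(norm, "F32") | startsWith(norm, "F33")
  d[, `:=`(
    n_e66 = as.integer(startsWith(norm, "E66")),
    n_f3main = as.integer(is_f3 & is_main),
    n_f3assoc = as.integer(is_f3 & !is_main),
    n_shassoc = as.integer(is_selfharm_code(norm, selfharm_upper_bound) &
                             !is_main),
    n_f3 = as.integer(is_f3)
  )]
  flagcols <- c("n_e66", "n_f3main", "n_f3assoc", "n_shassoc", "n_f3")
  agg <- d[, lapply(.SD, sum), by = stay_id, .SDcols = flagcols]
  first <- d[!duplicated(stay_id),
             .(stay_id, patient_id, source, geo_code, age, sex)]
  out <- first[agg, on = "stay_id"]
  mco <- out$source == "MCO"
  out[, obesity := mco & n_e66 > 0L]
  out[, depression := (mco & n_f3main > 0L) |
        (mco & n_shassoc > 0L & n_f3assoc > 0L) |
        (!mco & n_f3 > 0L)]
  out[, (flagcols) := NULL]
  out[, .(stay_id, patient_id, geo_code, age, sex, obesity, depression)]
}

#' Classify a single stay
#'
#' Convenience wrapper around [classify_stays()] for one stay given as a list
#' with fields `source` and `diagnoses` (a list of `(icd_code, role)` pairs).
#'
#' @param stay List with `source`, optional `stay_id`/`patient_id`/`geo_code`/
#'   `age`/`sex`, and `diagnoses`: list of lists with `icd_code` and `role`.
#' @param selfharm_upper_bound See [classify_stays()].
#' @return Character vector: subset of `c("obesity", "depression")`.
#' @export
classify_stay <- function(stay, selfharm_upper_bound = "X89") {
  stopifnot(length(stay$diagnoses) > 0)
  dt <- data.table::data.table(
    stay_id = stay$stay_id %||% 1L,
    patient_id = stay$patient_id %||% 1L,
    source = stay$source,
    geo_code = stay$geo_code %||% NA_character_,
    age = stay$age %||% NA_integer_,
    sex = stay$sex %||% NA_character_,
    diag_code = vapply(stay$diagnoses, `[[`, "", "icd_code"),
    diag_role = vapply(stay$diagnoses, `[[`, "", "role")
  )
  flags <- classify_stays(dt, selfharm_upper_bound)
  conditions()[c(flags$obesity, flags$depression)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_case_set <- function(condition, members) {
  structure(list(condition = condition,
                 members = data.table::as.data.table(members)),
            class = "case_set")
}

#' @export
print.case_set <- function(x, ...) {
  cat("<case_set>", x$condition, "-", nrow(x$members), "patients\n")
  invisible(x)
}

#' Select unique adult cases per condition
#'
#' Applies the stay-level classification, deduplicates to one membership per
#' patient and condition (a patient with several qualifying stays is counted
#' once; comorbid patients appear in both sets), takes each patient's
#' attributes from their first qualifying stay in input order, and drops
#' patients younger than 18 at that stay. Conflicting `sex` or `geo_code`
#' across a patient's qualifying stays are resolved by the first stay, with a
#' warning.
#'
#' @inheritParams classify_stays
#' @return Named list of two `case_set` objects (`obesity`, `depression`),
#'   each with a `members` table (`patient_id`, `geo_code`, `age`, `sex`).
#' @export
select_cases <- function(stays, selfharm_upper_bound = "X89") {
  flags <- classify_stays(stays, selfharm_upper_bound)
  pick <- function(cond) {
    qual <- flags[flags[[cond]] == TRUE]
    if (nrow(qual)) {
      combos <- unique(qual[, .(patient_id, sex, geo_code)])
      n_conflict <- nrow(combos) - data.table::uniqueN(combos$patient_id)
      if (n_conflict > 0L)
        warning(n_conflict, " conflicting sex/geo_code combination(s) ",
                "across stays of the same patient; resolved by first stay ",
                "in input order", call. = FALSE)
    }
    first <- qual[, .SD[1L], by = patient_id,
                  .SDcols = c("geo_code", "age", "sex")]
    new_case_set(cond, first[age >= 18])
  }
  list(obesity = pick("obesity"), depression = pick("depression"))
}

#' Cohort descriptives in the style of a baseline characteristics table
#'
#' Summarizes one or more case sets: mean (SD) age, percentage by sex, by
#' deprivation level and by urban typology, each evaluated at the patients'
#' geographic code. When exactly two case sets are given, two-sample
#' comparisons are added: Welch t-test for age, chi-square tests for the
#' categorical distributions.
#'
#' @param case_sets A `case_set` or named list of `case_set`s.
#' @param socio Areal socio-economic table (for `typology`).
#' @param deprivation [build_deprivation()] output (for `level`).
#' @return data.table with columns `block`, `label`, one value column per
#'   case set, and `p_value` (NA except on each block's first row when two
#'   sets are compared).
#' @export
describe_cohort <- function(case_sets, socio, deprivation) {
  if (inherits(case_sets, "case_set")) case_sets <- list(case_sets)
  if (is.null(names(case_sets)) || any(!nzchar(names(case_sets))))
    names(case_sets) <- vapply(case_sets, `[[`, "", "condition")
  socio <- data.table::as.data.table(socio)
  covar <- merge(socio[, .(geo_code, typology)],
                 deprivation[, .(geo_code, level)], by = "geo_code")

  members <- lapply(case_sets, function(cs) {
    m <- merge(cs$members, covar, by = "geo_code")
    if (nrow(m) < nrow(cs$members))
      stop("case geo_code(s) missing from socio/deprivation tables",
           call. = FALSE)
    m
  })

  level_labels <- c("Most advantaged", "National average", "Material deprivation",
                    "Social deprivation", "Most deprived")
  typo_labels <- c(major_urban = "Major urban centers",
                   suburbs = "Suburbs of major centers",
                   small_mid = "Small and mid-sized centers",
                   rural = "Rural areas")

  pct <- function(x, lev) 100 * as.vector(table(factor(x, levels = lev))) / length(x)
  block <- function(name, labels, values_by_set, p) {
    dt <- data.table::data.table(block = name, label = labels)
    for (nm in names(values_by_set)) dt[[nm]] <- values_by_set[[nm]]
    dt$p_value <- c(p, rep(NA_real_, nrow(dt) - 1L))
    dt
  }
  two <- length(members) == 2L
  chisq_p <- function(var, lev) {
    if (!two) return(NA_real_)
    counts <- vapply(members, function(m) {
      as.vector(table(factor(m[[var]], levels = lev)))
    }, numeric(length(lev)))
    keep <- rowSums(counts) > 0
    if (identical(counts[keep, 1], counts[keep, 2])) return(1)
    suppressWarnings(chisq.test(counts[keep, , drop = FALSE])$p.value)
  }
  age_p <- if (two) {
    a1 <- members[[1]]$age; a2 <- members[[2]]$age
    if (length(a1) > 1 && length(a2) > 1 && (sd(a1) > 0 || sd(a2) > 0))
      t.test(a1, a2)$p.value else NA_real_
  } else NA_real_

  out <- list(
    block("n", "Patients", lapply(members, nrow), NA_real_),
    block("age", c("Mean", "SD"),
          lapply(members, function(m) {
            c(mean(m$age), if (nrow(m) < 2L) 0 else sd(m$age))
          }), age_p),
    block("sex", c("Women", "Men"),
          lapply(members, function(m) pct(m$sex, c("F", "M"))),
          chisq_p("sex", c("F", "M"))),
    block("deprivation", level_labels,
          lapply(members, function(m) pct(m$level, 1:5)),
          chisq_p("level", 1:5)),
    block("typology", unname(typo_labels),
          lapply(members, function(m) pct(m$typology, typology_levels())),
          chisq_p("typology", typology_levels()))
  )
  data.table::rbindlist(out)
}
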