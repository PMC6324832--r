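# Pipeline orchestration: simulate (or read user data), select cases,
# standardize, deprivation index, overlap classification, bidirectional
# regression -- with schema validation on every file boundary and a manifest
# of output hashes for reproducibility checks.

schema_defs <- function() {
  list(
    census = list(
      columns = c(geo_code = "character", age_band = "character",
                  sex = "character", population = "integer"),
      checks = list(
        list(col = "population", fn = function(x) x >= 0,
             msg = "population must be non-negative"),
        list(col = "sex", fn = function(x) x %in% c("F", "M"),
             msg = "sex must be one of F, M"),
        list(col = "age_band", fn = function(x) x %in% age_band_levels(),
             msg = paste("age_band must be one of:",
                         paste(age_band_levels(), collapse = ", "))))),
    socio = list(
      columns = c(geo_code = "character", unemployment = "numeric",
                  blue_collar = "numeric", low_diploma = "numeric",
                  immigrant = "numeric", non_taxable = "numeric",
                  typology = "character"),
      checks = c(
        lapply(c("unemployment", "blue_collar", "low_diploma", "immigrant",
                 "non_taxable"), function(v)
                   list(col = v, fn = function(x) x >= 0 & x <= 1,
                        msg = paste(v, "must lie in [0, 1]"))),
        list(list(col = "typology", fn = function(x) x %in% typology_levels(),
                  msg = paste("typology must be one of:",
                              paste(typology_levels(), collapse = ", ")))))),
    stays = list(
      columns = c(stay_id = "any", patient_id = "any", source = "character",
                  geo_code = "character", age = "integer", sex = "character",
                  diag_code = "character", diag_role = "character"),
      checks = list(
        list(col = "source", fn = function(x) x %in% c("MCO", "RIMP"),
             msg = "source must be one of MCO, RIMP"),
        list(col = "sex", fn = function(x) x %in% c("F", "M"),
             msg = "sex must be one of F, M"),
        list(col = "diag_role", fn = function(x) x %in% c("main", "associated"),
             msg = "diag_role must be one of main, associated"),
        list(col = "age", fn = function(x) x >= 0,
             msg = "age must be non-negative"))),
    rates = list(
      columns = c(geo_code = "character", condition = "character",
                  cases = "integer", crude = "numeric",
                  standardized = "numeric"),
      checks = list(
        list(col = "condition", fn = function(x) x %in% conditions(),
             msg = "condition must be one of obesity, depression"),
        list(col = "cases", fn = function(x) x >= 0,
             msg = "cases must be non-negative")))
  )
}

#' Validate a delimited file (or table) against a named schema
#'
#' Checks column presence, coercibility to the expected types, and domain
#' constraints (shares in `[0,1]`, enumerated labels, non-negative counts).
#' Violations carry 1-based data row numbers.
#'
#' @param file Path to a delimited text file, or a data.frame/data.table.
#' @param schema_name One of `"census"`, `"socio"`, `"stays"`, `"rates"`.
#' @param delimiter Field delimiter when reading from disk (default `","`).
#' @return List: `ok` (logical) and `violations` (character vector, empty
#'   when valid).
#' @export
validate_schema <- function(file, schema_name, delimiter = ",") {
  defs <- schema_defs()
  if (!schema_name %in% names(defs))
    stop("unknown schema '", schema_name, "'", call. = FALSE)
  def <- defs[[schema_name]]
  dt <- if (is.data.frame(file)) data.table::as.data.table(file)
        else {
          if (!file.exists(file)) stop("unreadable file: ", file, call. = FALSE)
          data.table::fread(file, sep = delimiter, colClasses = "character")
        }
  violations <- character(0)
  missing <- setdiff(names(def$columns), names(dt))
  if (length(missing))
    violations <- c(violations,
                    paste("missing column(s):", paste(missing, collapse = ", ")))
  for (chk in def$checks) {
    if (!chk$col %in% names(dt)) next
    x <- dt[[chk$col]]
    expected <- def$columns[[chk$col]]
    if (expected %in% c("integer", "numeric")) {
      x <- suppressWarnings(as.numeric(x))
      bad_type <- which(is.na(x) & !is.na(dt[[chk$col]]))
      if (length(bad_type))
        violations <- c(violations, paste0(
          chk$col, ": non-numeric value(s) at row(s) ",
          paste(head(bad_type, 5), collapse = ", ")))
    }
    ok <- chk$fn(x)
    bad <- which(!ok | is.na(ok))
    if (length(bad))
      violations <- c(violations, paste0(
        chk$col, ": ", chk$msg, " (row(s) ",
        paste(head(bad, 5), collapse = ", "),
        if (length(bad) > 5) ", ..." else "", ")"))
  }
  list(ok = length(violations) == 0L, violations = violations)
}

read_validated <- function(path, schema_name, delimiter = ",") {
  v <- validate_schema(path, schema_name, delimiter)
  if (!v$ok)
    stop("schema violations in ", path, " [", schema_name, "]:\n  ",
         paste(v$violations, collapse = "\n  "), call. = FALSE)
  data.table::fread(path, sep = delimiter)
}

#' Run the full pipeline from one configuration
#'
#' Either simulates a dataset (when `config$sim` is a [sim_config()]) or reads
#' user data from `config$paths` (named: `stays`, `census`, `socio`), then runs
#' selection, standardization, the deprivation index, the overlap
#' classification and both ecological regressions, writing every artifact to
#' `config$out_dir` together with a manifest of MD5 hashes and a run log.
#' Identical configuration (including seed) yields identical manifests.
#'
#' @param config List with `out_dir`, and exactly one of `sim` (a
#'   [sim_config()]) or `paths`; optional `selfharm_upper_bound`
#'   (default `"X89"`) and `delimiter` (default `","`).
#' @return Invisibly, the manifest (named MD5 vector over output files).
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) stop("config$out_dir is required", call. = FALSE)
  has_sim <- !is.null(config$sim)
  has_paths <- !is.null(config$paths)
  if (has_sim == has_paths)
    stop("exactly one of config$sim and config$paths must be given",
         call. = FALSE)
  shb <- config$selfharm_upper_bound %||% "X89"
  delim <- config$delimiter %||% ","
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(paste("pipeline run,", "R", getRversion()),
                 paste("selfharm_upper_bound:", shb))

  if (has_sim) {
    validate_sim_config(config$sim)
    log_lines <- c(log_lines, paste("simulated, seed:", config$sim$seed))
    paths <- write_simulation(config$sim, out_dir)
    census <- data.table::fread(paths[["census"]])
    socio_path <- paths[["socio"]]
    stays_path <- paths[["stays"]]
  } else {
    for (p in c("stays", "census", "socio"))
      if (is.null(config$paths[[p]]) || !file.exists(config$paths[[p]]))
        stop("missing input file for '", p, "'", call. = FALSE)
    census <- read_validated(config$paths$census, "census", delim)
    socio_path <- config$paths$socio
    stays_path <- config$paths$stays
  }
  socio <- read_validated(socio_path, "socio", delim)
  stays <- read_validated(stays_path, "stays", delim)
  chk <- validate_schema(census, "census")
  if (!chk$ok) stop("census schema: ", paste(chk$violations, collapse = "; "),
                    call. = FALSE)

  sel <- select_cases(stays, selfharm_upper_bound = shb)
  for (cond in conditions())
    data.table::fwrite(sel[[cond]]$members,
                       file.path(out_dir, paste0("cases_", cond, ".csv")))

  depr <- build_deprivation(socio)
  data.table::fwrite(depr, file.path(out_dir, "deprivation.csv"))

  tab1 <- describe_cohort(sel, socio, depr)
  data.table::fwrite(tab1, file.path(out_dir, "table1.csv"))

  rates <- areal_rates(sel, census)
  data.table::fwrite(rates, file.path(out_dir, "rates.csv"))

  national <- vapply(conditions(), function(cond)
    national_rate(sel[[cond]], census), numeric(1))
  ov <- classify_overlap(rates, national)
  data.table::fwrite(ov$table, file.path(out_dir, "overlap.csv"))
  data.table::fwrite(class_shares(ov), file.path(out_dir, "overlap_shares.csv"))

  reg <- run_bidirectional(rates, depr, socio)
  data.table::fwrite(reg$obesity$table, file.path(out_dir, "table2.csv"))
  data.table::fwrite(reg$depression$table, file.path(out_dir, "table3.csv"))

  outputs <- c("census.csv", "socio.csv", "stays.csv", "truth.json",
               "cases_obesity.csv", "cases_depression.csv", "deprivation.csv",
               "table1.csv", "rates.csv", "overlap.csv", "overlap_shares.csv",
               "table2.csv", "table3.csv")
  outputs <- outputs[file.exists(file.path(out_dir, outputs))]
  manifest <- tools::md5sum(file.path(out_dir, outputs))
  names(manifest) <- outputs
  jsonlite::write_json(as.list(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(manifest)
}
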