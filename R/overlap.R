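# High/Low co-prevalence classification of codes against national reference
# rates: first letter = obesity vs national average, second = depression.
# A code is High on a dimension iff its standardized rate strictly exceeds the
# national reference (ties are Low, fixed for determinism).

#' Classify one code against the national reference rates
#'
#' @param rate_obesity,rate_depression Standardized areal rates per 100,000.
#' @param national_obesity,national_depression National reference rates.
#' @return One of `"HH"`, `"HL"`, `"LH"`, `"LL"`.
#' @export
classify_code <- function(rate_obesity, rate_depression,
                          national_obesity, national_depression) {
  vals <- c(rate_obesity, rate_depression, national_obesity, national_depression)
  if (any(!is.finite(vals))) stop("non-finite rate", call. = FALSE)
  paste0(ifelse(rate_obesity > national_obesity, "H", "L"),
         ifelse(rate_depression > national_depression, "H", "L"))
}

#' Classify every code into the four co-prevalence classes
#'
#' Codes with a missing standardized rate for either condition (zero
#' population) are excluded with a message.
#'
#' @param rates Long areal rates table from [areal_rates()].
#' @param national Named numeric: national reference rates per 100,000 for
#'   `obesity` and `depression`.
#' @return Object of class `overlap_classification`: list with `table`
#'   (`geo_code`, `class`), `national`, and `n_excluded`.
#' @export
classify_overlap <- function(rates, national) {
  stopifnot(all(conditions() %in% names(national)))
  wide <- data.table::dcast(data.table::as.data.table(rates),
                            geo_code ~ condition, value.var = "standardized")
  bad <- !complete.cases(wide)
  if (any(bad))
    message(sum(bad), " code(s) without computable rates excluded from overlap")
  wide <- wide[!bad]
  if (!nrow(wide)) stop("no codes with computable rates", call. = FALSE)
  wide[, class := paste0(ifelse(obesity > national[["obesity"]], "H", "L"),
                         ifelse(depression > national[["depression"]], "H", "L"))]
  structure(list(table = wide[, .(geo_code, class)],
                 national = national[conditions()],
                 n_excluded = sum(bad)),
            class = "overlap_classification")
}

#' Share of codes in each co-prevalence class
#'
#' @param classification An `overlap_classification`.
#' @return data.table with one row per class (`HH`, `HL`, `LH`, `LL`)
#'   holding `n` and `share_pct`, plus a `conjoint` row (`HH` + `LL`, the
#'   share of codes where both conditions lie on the same side of the
#'   national average).
#' @export
class_shares <- function(classification) {
  stopifnot(inherits(classification, "overlap_classification"))
  tab <- classification$table
  if (!nrow(tab)) stop("empty classification", call. = FALSE)
  counts <- table(factor(tab$class, levels = c("HH", "HL", "LH", "LL")))
  out <- data.table::data.table(class = names(counts),
                                n = as.integer(counts),
                                share_pct = 100 * as.integer(counts) / nrow(tab))
  conjoint <- out[class %in% c("HH", "LL"),
                  .(class = "conjoint", n = sum(n), share_pct = sum(share_pct))]
  data.table::rbindlist(list(out, conjoint))
}
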