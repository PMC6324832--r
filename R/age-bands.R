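# Age bands for the adult (18+) analysis population: an 18-19 sliver keeps the
# >= 18 inclusion rule exact, then decennial bands up to 90+.

#' Age bands used throughout the pipeline
#'
#' The analysis population is restricted to adults (age 18 and over). Bands are
#' decennial except for the 18-19 sliver, which makes the adult filter align
#' exactly with the band edges, and an open-ended 90+ band.
#'
#' @return Character vector of band labels, in increasing age order.
#' @export
age_band_levels <- function() {
  c("18-19", "20-29", "30-39", "40-49", "50-59", "60-69", "70-79", "80-89", "90+")
}

#' Map integer ages to age bands
#'
#' @param age Integer vector of ages in years.
#' @return Factor with levels [age_band_levels()]; ages below 18 map to `NA`.
#' @export
age_band_of <- function(age) {
  stopifnot(is.numeric(age))
  breaks <- c(18, 20, seq(30, 90, by = 10), Inf)
  cut(age, breaks = breaks, labels = age_band_levels(), right = FALSE)
}

# Inclusive integer age range of each band (90+ truncated at 99 for sampling).
band_age_range <- function(band) {
  lo <- c(`18-19` = 18, `20-29` = 20, `30-39` = 30, `40-49` = 40, `50-59` = 50,
          `60-69` = 60, `70-79` = 70, `80-89` = 80, `90+` = 90)
  hi <- c(`18-19` = 19, `20-29` = 29, `30-39` = 39, `40-49` = 49, `50-59` = 59,
          `60-69` = 69, `70-79` = 79, `80-89` = 89, `90+` = 99)
  cbind(lo = lo[band], hi = hi[band])
}

#' Urban/rural typology labels
#'
#' Four aggregated categories of the urbanization typology carried as an
#' areal covariate: major urban centers, their suburbs, small and mid-sized
#' centers, and rural areas.
#'
#' @return Character vector of the four labels.
#' @export
typology_levels <- function() {
  c("major_urban", "suburbs", "small_mid", "rural")
}

conditions <- function() c("obesity", "depression")
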