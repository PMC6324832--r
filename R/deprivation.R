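# Bidimensional material/social deprivation index (Pampalon-style).
#
# Social score: mean of the z-scores (across codes) of unemployment,
# blue-collar, low-diploma and immigrant shares, re-standardized to SD 1.
# Material score: z-score of the non-taxable-household share.
# Each score is cut into 3 classes at -1/+1 SD and the two classes are crossed
# into 5 deprivation levels.

social_components <- function() {
  c("unemployment", "blue_collar", "low_diploma", "immigrant")
}

zscore <- function(x, what) {
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop("zero-variance component '", what, "': z-score undefined",
         call. = FALSE)
  (x - mean(x)) / s
}

#' Standardized social and material deprivation scores
#'
#' @param socio Areal socio-economic table with the five indicator shares.
#' @return data.table: `geo_code`, `z_social`, `z_material` (each mean 0,
#'   SD 1 across codes; higher = more deprived).
#' @export
compute_scores <- function(socio) {
  socio <- data.table::as.data.table(socio)
  if (nrow(socio) < 3L) stop("need at least 3 codes", call. = FALSE)
  zs <- sapply(social_components(), function(v) zscore(socio[[v]], v))
  z_social <- zscore(rowMeans(zs), "social score")
  z_material <- zscore(socio$non_taxable, "non_taxable")
  data.table::data.table(geo_code = socio$geo_code,
                         z_social = z_social, z_material = z_material)
}

#' Three-class cut of a standardized score
#'
#' Borders at -1 and +1 standard deviations; values exactly on a border fall
#' in the middle class (strict inequalities for classes 1 and 3).
#'
#' @param z Numeric score vector (finite).
#' @return Integer vector in `{1, 2, 3}`: 1 below -1 SD, 3 above +1 SD,
#'   2 otherwise.
#' @export
classify_score <- function(z) {
  if (any(!is.finite(z))) stop("non-finite score", call. = FALSE)
  ifelse(z < -1, 1L, ifelse(z > 1, 3L, 2L))
}

#' Cross material and social classes into the 5-level deprivation index
#'
#' Levels: 1 most advantaged (both classes 1); 2 national average (the three
#' residual cells with no class-3 component and at least one class 2);
#' 3 material deprivation (material class 3, social class 1 or 2); 4 social
#' deprivation (social class 3, material class 1 or 2); 5 most deprived (both
#' classes 3). Total over the 9-cell grid.
#'
#' @param class_material,class_social Integer vectors in `{1, 2, 3}`.
#' @return Integer vector of levels in `{1, ..., 5}`.
#' @export
cross_levels <- function(class_material, class_social) {
  ok <- function(x) all(x %in% 1:3)
  if (!ok(class_material) || !ok(class_social))
    stop("classes must lie in {1, 2, 3}", call. = FALSE)
  lvl <- rep(2L, length(class_material))
  lvl[class_material == 1L & class_social == 1L] <- 1L
  lvl[class_material == 3L & class_social <= 2L] <- 3L
  lvl[class_material <= 2L & class_social == 3L] <- 4L
  lvl[class_material == 3L & class_social == 3L] <- 5L
  lvl
}

#' Full deprivation profile of every code
#'
#' @param socio Areal socio-economic table.
#' @return data.table: `geo_code`, `z_social`, `z_material`, `class_social`,
#'   `class_material`, `level`.
#' @export
build_deprivation <- function(socio) {
  sc <- compute_scores(socio)
  sc[, `:=`(class_social = classify_score(z_social),
            class_material = classify_score(z_material))]
  sc[, level := cross_levels(class_material, class_social)]
  sc[]
}
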