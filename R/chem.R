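#' Percent acetyl-bromide soluble lignin (%ABSL)
#'
#' Beer--Lambert conversion of an acetyl-bromide digest absorbance into
#' percent soluble lignin:
#' \deqn{\%ABSL = \frac{A}{\varepsilon \cdot l} \cdot
#'       \frac{V}{m} \cdot 100}
#' with absorbance \eqn{A}, extinction coefficient \eqn{\varepsilon}
#' (absorbance mL mg^-1 cm^-1; default 17.2, the tobacco-family stem
#' coefficient used for tomato), light path \eqn{l} in cm (default 1.0,
#' a 10-mm cuvette), digest volume \eqn{V} in mL and biomass \eqn{m} in
#' mg.
#'
#' @param absorbance measured absorbance (dimensionless, >= 0).
#' @param biomass_mg biomass in mg (> 0).
#' @param volume_mL digest volume in mL (> 0).
#' @param path_cm cuvette light path in cm (default 1.0).
#' @param extinction extinction coefficient (default 17.2).
#' @return Percent ABSL (numeric; vectorised over its arguments).
#' @examples
#' absl_percent(17.2, biomass_mg = 100, volume_mL = 1)  # 1.0
#' @export
absl_percent <- function(absorbance, biomass_mg, volume_mL,
                         path_cm = 1.0, extinction = 17.2) {
  if (any(absorbance < 0)) stopf("absorbance must be >= 0")
  if (any(biomass_mg <= 0)) stopf("biomass_mg must be positive")
  if (any(volume_mL <= 0)) stopf("volume_mL must be positive")
  if (any(path_cm <= 0)) stopf("path_cm must be positive")
  if (any(extinction <= 0)) stopf("extinction must be positive")
  absorbance / (extinction * path_cm) * (volume_mL / biomass_mg) * 100
}

#' Normalise pyrolysis-GC/MS peak areas into monolignol composition
#'
#' Divides each compound's peak area by the sample's summed area and
#' aggregates the per-compound fractions into monolignol classes (H, G,
#' S, p-coumarate, other). Fractions sum to 1; multiplying all areas by
#' a positive constant leaves them unchanged.
#'
#' @param table data frame with columns `compound`, `class` (one of
#'   `"H"`, `"G"`, `"S"`, `"p-coumarate"`, `"other"`) and `area` (>= 0,
#'   total > 0).
#' @return List with `compounds` (the input plus a `fraction` column)
#'   and `classes` (data frame: class, fraction).
#' @export
normalize_pyrogram <- function(table) {
  need <- c("compound", "class", "area")
  if (!all(need %in% names(table))) {
    stopf("pyrogram table needs columns compound, class, area")
  }
  classes <- c("H", "G", "S", "p-coumarate", "other")
  if (!all(table$class %in% classes)) {
    stopf("class must be one of: %s", paste(classes, collapse = ", "))
  }
  if (any(table$area < 0)) stopf("areas must be >= 0")
  tot <- sum(table$area)
  if (tot == 0) stopf("all peak areas are zero")
  out <- table
  out$fraction <- out$area / tot
  cls <- aggregate(fraction ~ class, data = out, FUN = sum)
  cls <- cls[match(intersect(classes, cls$class), cls$class), ]
  rownames(cls) <- NULL
  list(compounds = out, classes = cls)
}
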