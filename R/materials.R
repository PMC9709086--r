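#' Material presets for samples and immersion media
#'
#' Refractive indices and nominal elastic moduli of the reference materials
#' used throughout: polystyrene (PS), polyacrylamide (PAA) and agarose
#' microbeads, and the immersion media (deionized water, DMEM/F12 culture
#' medium, glycerol).  Bead indices are the literature values at 589 nm;
#' nominal stiffness values are the vendor/ensemble means (PS 1.05 GPa,
#' PAA 1.94 kPa, agarose 2.43 kPa).  Media carry no stiffness.
#'
#' @param name preset name, one of \code{"PS"}, \code{"PAA"},
#'   \code{"agarose"}, \code{"water"}, \code{"DMEM/F12"}, \code{"glycerol"},
#'   \code{"cell"}, \code{"cell_treated"}
#' @return an object of class \code{material} with fields \code{name},
#'   \code{refractive_index}, \code{nominal_stiffness} (Pa or \code{NA}),
#'   \code{nominal_diameter} (um or \code{NA}) and \code{medium} flag
#' @examples
#' material("PS")$refractive_index   # 1.5915
#' material("water")$refractive_index # 1.334
#' @export
material <- function(name) {
  tab <- material_table()
  row <- tab[tab$name == name, ]
  if (nrow(row) != 1L) {
    stop("unknown material preset '", name, "'; see material_table()")
  }
  out <- list(name = row$name,
              refractive_index = row$refractive_index,
              nominal_stiffness = row$nominal_stiffness,
              nominal_diameter = row$nominal_diameter,
              medium = row$medium)
  class(out) <- "material"
  out
}

#' Table of all material presets
#'
#' @return data.frame with one row per preset: \code{name},
#'   \code{refractive_index} (dimensionless), \code{nominal_stiffness} (Pa,
#'   \code{NA} for media), \code{nominal_diameter} (um, \code{NA} where not
#'   applicable), \code{medium} (logical)
#' @export
material_table <- function() {
  data.frame(
    name = c("PS", "PAA", "agarose", "water", "DMEM/F12", "glycerol",
             "cell", "cell_treated"),
    refractive_index = c(1.5915, 1.349, 1.3329, 1.334, 1.337, 1.4722,
                         1.375, 1.375),
    nominal_stiffness = c(1.05e9, 1.94e3, 2.43e3, NA, NA, NA,
                          1.08e3, 0.88e3),
    nominal_diameter = c(5, 31, 34.7, NA, NA, NA, 16, 16),
    medium = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s  n = %.4f", x$name, x$refractive_index))
  if (!is.na(x$nominal_stiffness)) {
    cat(sprintf("  E = %.3g Pa", x$nominal_stiffness))
  }
  if (isTRUE(x$medium)) cat("  (medium)")
  cat("\n")
  invisible(x)
}

validate_material <- function(m) {
  stopifnot(inherits(m, "material"))
  if (m$refractive_index <= 1) stop("refractive index must exceed 1")
  if (!is.na(m$nominal_stiffness) && m$nominal_stiffness <= 0) {
    stop("nominal stiffness must be positive when present")
  }
  invisible(m)
}
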