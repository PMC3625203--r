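# Physical constants and per-element reference data.
#
# All unit conversions in the package go through the constants defined here
# (CODATA 2018).  User-facing coordinates are in angstrom; everything inside
# the energy machinery is in atomic units (bohr, hartree).

#' Unit conversion constants
#'
#' CODATA 2018 values used throughout the package.  Coordinates are angstrom
#' in files and in the user API, bohr internally; energies are hartree
#' internally and kcal/mol in reaction-profile reports.
#'
#' @format A named list with elements `bohr_to_angstrom`,
#'   `angstrom_to_bohr`, `hartree_to_kcalmol` and `kcalmol_to_hartree`.
#' @export
efmo_units <- local({
  b2a <- 0.529177210903
  h2k <- 627.5094740631
  list(
    bohr_to_angstrom = b2a,
    angstrom_to_bohr = 1 / b2a,
    hartree_to_kcalmol = h2k,
    kcalmol_to_hartree = 1 / h2k
  )
})

# Bondi van der Waals radii (angstrom).  These normalize the unitless
# interfragment distance, so they are frozen here rather than taken from an
# external source at run time.
.vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  P = 1.80, S = 1.80, Cl = 1.75, Na = 2.27, K = 2.75
)

# Pyykko single-bond covalent radii (angstrom); used for bond detection and
# for the mock backend's equilibrium bond lengths.
.covalent_radii <- c(
  H = 0.32, C = 0.75, N = 0.71, O = 0.63, F = 0.64,
  P = 1.11, S = 1.03, Cl = 0.99, Na = 1.55, K = 1.96
)

.known_elements <- names(.vdw_radii)

#' Van der Waals radius of an element
#'
#' Bondi radii, in angstrom.  These radii normalize the unitless
#' interfragment distance, so they are part of the package's frozen reference
#' data.
#'
#' @param element Character vector of element symbols.
#' @return Numeric vector of radii (angstrom).
#' @export
vdw_radius <- function(element) {
  r <- .vdw_radii[element]
  if (anyNA(r)) {
    stop("no van der Waals radius for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

#' Covalent radius of an element
#'
#' Pyykko single-bond covalent radii, in angstrom.
#'
#' @inheritParams vdw_radius
#' @return Numeric vector of radii (angstrom).
#' @export
covalent_radius <- function(element) {
  r <- .covalent_radii[element]
  if (anyNA(r)) {
    stop("no covalent radius for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

# Normalize an element symbol: "CL" -> "Cl", " o" -> "O".
.normalize_element <- function(x) {
  x <- gsub("[^A-Za-z]", "", x)
  bad <- !nzchar(x)
  x <- paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
  x[bad] <- NA_character_
  x
}
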