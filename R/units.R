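# Physical constants and unit conversions.  Internal conventions:
# coordinates in Angstrom, model energies in the unit the training data
# carried (cm^-1 for PIP models by default, kcal/mol for the force field);
# conversions happen at I/O and reporting boundaries.

#' Unit conversion constants
#'
#' Named constants used throughout the package: `bohr_to_angstrom`
#' (0.52917721067), `hartree_to_cm1` (219474.6313632), `kcalmol_to_cm1`
#' (349.755), and the SI quantities needed to convert mass-weighted Hessian
#' eigenvalues to wavenumbers.
#'
#' @format A named list of numeric scalars.
#' @export
pes_constants <- list(
  bohr_to_angstrom = 0.52917721067,
  hartree_to_cm1   = 219474.6313632,
  kcalmol_to_cm1   = 349.755,
  # SI helpers for frequency conversion
  cm1_to_joule     = 1.9864458571489287e-23, # 100 * h * c
  kcalmol_to_joule = 4184 / 6.02214076e23,
  amu_to_kg        = 1.66053906660e-27,
  speed_of_light   = 2.99792458e8            # m/s
)

#' Convert energies between units
#'
#' Supported units: `"cm-1"`, `"kcal/mol"`, `"hartree"`.  All conversions
#' go through cm^-1 using the package constants and round-trip to better
#' than 1e-12 relative error.
#'
#' @param x numeric vector of energies.
#' @param from,to unit names.
#' @return numeric vector in the target unit.
#' @export
convert_energy <- function(x, from, to) {
  fac <- function(u) {
    switch(match.arg(u, c("cm-1", "kcal/mol", "hartree")),
      "cm-1" = 1,
      "kcal/mol" = pes_constants$kcalmol_to_cm1,
      "hartree" = pes_constants$hartree_to_cm1
    )
  }
  x * (fac(from) / fac(to))
}

#' Convert lengths between units
#'
#' Supported units: `"angstrom"`, `"bohr"`.
#'
#' @param x numeric vector of lengths.
#' @param from,to unit names.
#' @return numeric vector in the target unit.
#' @export
convert_length <- function(x, from, to) {
  fac <- function(u) {
    switch(match.arg(u, c("angstrom", "bohr")),
      "angstrom" = 1,
      "bohr" = pes_constants$bohr_to_angstrom
    )
  }
  x * (fac(from) / fac(to))
}

# Standard atomic weights (default) and most-abundant-isotope masses, amu.
.mass_tables <- list(
  standard = c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
               F = 18.998403163, S = 32.06, Cl = 35.45),
  isotope  = c(H = 1.00782503207, C = 12.0, N = 14.0030740048,
               O = 15.99491461956, F = 18.99840316273, S = 31.97207100,
               Cl = 34.96885268)
)

#' Atomic masses for a vector of element symbols
#'
#' @param elements character vector of element symbols (case-insensitive).
#' @param convention `"standard"` atomic weights (default) or `"isotope"`
#'   most-abundant-isotope masses.  The frequency tables this package
#'   produces depend mildly on the choice; both are supported and the
#'   convention used is recorded in [normal_modes()] output.
#' @return numeric vector of masses in amu.
#' @export
atomic_masses <- function(elements, convention = c("standard", "isotope")) {
  convention <- match.arg(convention)
  tab <- .mass_tables[[convention]]
  el <- canonical_element(elements)
  unknown <- setdiff(unique(el), names(tab))
  if (length(unknown) > 0)
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  unname(tab[el])
}

canonical_element <- function(elements) {
  el <- as.character(elements)
  paste0(toupper(substr(el, 1, 1)),
         tolower(substr(el, 2, nchar(el))))
}
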