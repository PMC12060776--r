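#' Physical constants and unit conversions
#'
#' All user-facing quantities use eV, Angstrom, fs, amu and elementary
#' charges; electric fields are in atomic units (Hartree/(e*bohr)).
#' Every conversion used anywhere in the package is centralised here so
#' that training labels and dynamics can never drift apart in units.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{bohr_ang}{Bohr radius in Angstrom.}
#'   \item{hartree_ev}{Hartree in eV.}
#'   \item{coulomb_ev_ang}{e^2/(4 pi eps0) in eV*Angstrom (Coulomb's law
#'     prefactor for charges in e and distances in Angstrom).}
#'   \item{field_au_ev}{Energy in eV of a 1 e*Angstrom dipole in a unit
#'     atomic-units field.}
#'   \item{kB_ev}{Boltzmann constant in eV/K.}
#'   \item{hbar_ev_fs}{Reduced Planck constant in eV*fs.}
#'   \item{acc_conv}{Conversion so that acceleration in Angstrom/fs^2 equals
#'     \code{acc_conv * F[eV/Angstrom] / m[amu]}; its inverse converts
#'     amu*(Angstrom/fs)^2 to eV.}
#'   \item{ev_kcalmol}{1 eV in kcal/mol.}
#' }
#' @export
fh_const <- list(
  bohr_ang      = 0.529177210903,
  hartree_ev    = 27.211386245988,
  coulomb_ev_ang = 27.211386245988 * 0.529177210903,
  field_au_ev   = 27.211386245988 / 0.529177210903,
  kB_ev         = 8.617333262e-5,
  hbar_ev_fs    = 0.6582119569,
  acc_conv      = 9.64853321e-3,
  ev_kcalmol    = 23.060547830619026
)

#' Standard atomic masses for the elements used by the oracle systems
#' @noRd
.fh_masses <- c("1" = 1.00782503207, "6" = 12.0, "7" = 14.0030740048,
                "8" = 15.99491461956, "16" = 31.97207100)

#' Element symbols for a handful of light elements
#' @noRd
.fh_symbols <- c("1" = "H", "6" = "C", "7" = "N", "8" = "O", "16" = "S")

#' @noRd
.fh_numbers <- stats::setNames(as.integer(names(.fh_symbols)), .fh_symbols)

#' Look up element symbols from atomic numbers
#' @param z integer vector of atomic numbers
#' @return character vector of element symbols
#' @keywords internal
element_symbol <- function(z) {
  s <- .fh_symbols[as.character(z)]
  s[is.na(s)] <- paste0("Z", z[is.na(s)])
  unname(s)
}

#' Look up atomic numbers from element symbols
#' @param sym character vector of element symbols
#' @return integer vector of atomic numbers
#' @keywords internal
element_number <- function(sym) {
  z <- .fh_numbers[sym]
  if (anyNA(z)) stop("unknown element symbol: ", paste(sym[is.na(z)], collapse = ", "))
  unname(z)
}

#' Default atomic mass (amu) for atomic numbers
#' @param z integer vector of atomic numbers
#' @return numeric vector of masses in amu
#' @keywords internal
element_mass <- function(z) {
  m <- .fh_masses[as.character(z)]
  if (anyNA(m)) stop("no tabulated mass for Z = ", paste(z[is.na(m)], collapse = ", "))
  unname(m)
}
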