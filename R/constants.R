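#' Physical constants and element data
#'
#' All internal computation uses Hartree atomic units; magnetic operators
#' follow the Gaussian-CGS convention, i.e. they carry explicit factors of
#' 1/c with c the speed of light in atomic units.  The constants here are
#' the single source of unit conversions for the whole package.
#'
#' @format A list with elements:
#' \describe{
#'   \item{bohr_per_angstrom}{length conversion, CODATA-2018}
#'   \item{c_au}{speed of light in atomic units (inverse fine-structure
#'     constant)}
#'   \item{amu_to_me}{atomic mass unit in electron masses}
#'   \item{hartree_to_cm1}{energy conversion to wavenumbers}
#'   \item{dipole_strength_au_to_1e40esu2cm2}{(e a0)^2 expressed in
#'     10^-40 esu^2 cm^2}
#'   \item{rot_strength_au_to_1e44esu2cm2}{(e a0)^2 expressed in
#'     10^-44 esu^2 cm^2 (in Gaussian units electric and magnetic dipoles
#'     share the dimension esu cm, so the same base factor applies)}
#' }
#' @export
phys_constants <- list(
  bohr_per_angstrom = 1 / 0.529177210903,
  angstrom_per_bohr = 0.529177210903,
  c_au = 137.035999084,
  amu_to_me = 1822.888486209,
  hartree_to_cm1 = 219474.6313632,
  # (e a0)^2 = (4.80320471e-10 esu * 0.529177210903e-8 cm)^2
  dipole_strength_au_to_1e40esu2cm2 = 64604.8,
  rot_strength_au_to_1e44esu2cm2 = 646048000
)

# isotope-averaged masses (amu); nuclear charge by symbol
.element_table <- data.frame(
  symbol = c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne"),
  Z = 1:10,
  mass = c(1.008, 4.002602, 6.94, 9.0121831, 10.81, 12.011,
           14.007, 15.999, 18.998403163, 20.1797),
  stringsAsFactors = FALSE
)

#' Look up element data by symbol
#'
#' @param symbol element symbol, e.g. "O"
#' @return list with `Z` (nuclear charge) and `mass` (amu)
#' @export
element_info <- function(symbol) {
  i <- match(symbol, .element_table$symbol)
  if (is.na(i)) stop("unknown element symbol: ", symbol)
  list(Z = .element_table$Z[i], mass = .element_table$mass[i])
}
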