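#' Physical constants used throughout the package
#'
#' CODATA values, centralised so that every module shares a single unit
#' convention: separations in Angstrom, energies in kJ/mol, temperatures in
#' kelvin, second virial coefficients in cm^3/mol, atomic masses in unified
#' atomic mass units.
#'
#' @format A named list:
#' \describe{
#'   \item{N_A}{Avogadro constant, 1/mol}
#'   \item{k_B}{Boltzmann constant, J/K}
#'   \item{hbar}{reduced Planck constant, J s}
#'   \item{R_kJ}{molar gas constant, kJ/(mol K)}
#'   \item{amu}{unified atomic mass unit, kg}
#' }
#' @export
#' @examples
#' vdw_constants$R_kJ * 100 # RT at 100 K in kJ/mol
vdw_constants <- list(
  N_A  = 6.02214076e23,
  k_B  = 1.380649e-23,
  hbar = 1.054571817e-34,
  R_kJ = 8.31446261815324e-3,
  amu  = 1.66053906660e-27
)
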