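#' Physical constants used throughout the package
#'
#' Electrostatic energies are carried internally in kcal/mol with lengths in
#' Angstrom and charges in elementary charge units; potentials are then in
#' kcal/mol/e and converted to mV on output.  All constants derive from CODATA
#' values so that e.g. the Nernstian slope RT ln10 / F at 300 K comes out as
#' 59.52 mV/pH rather than a rounded literature figure.
#'
#' @format A named list:
#' \describe{
#'   \item{coulomb}{Coulomb constant, 332.0637 kcal mol^-1 A e^-2.}
#'   \item{R_kcal}{Gas constant, 1.9872041e-3 kcal mol^-1 K^-1.}
#'   \item{mV_per_kcal}{Conversion 1 kcal/mol = 43.364 mV for a unit charge
#'     (1 eV = 23.0605 kcal/mol).}
#'   \item{kcal_per_mV}{Inverse conversion, 0.0230605 kcal/mol per mV.}
#'   \item{kT300_eV}{Thermal energy at 300 K in eV, 0.025851.}
#' }
#' @export
PHYS <- list(
  coulomb     = 332.0637,         # kcal*A/(mol*e^2)
  R_kcal      = 1.9872041e-3,     # kcal/(mol*K)
  eV_per_kcal = 1 / 23.0605,      # eV per kcal/mol
  kcal_per_eV = 23.0605,
  mV_per_kcal = 1000 / 23.0605,   # 43.364 mV per kcal/mol (unit charge)
  kcal_per_mV = 23.0605 / 1000,   # 0.0230605
  kB_SI       = 1.380649e-23,     # J/K
  e_SI        = 1.602176634e-19,  # C
  NA_SI       = 6.02214076e23,    # 1/mol
  eps0_SI     = 8.8541878128e-12, # F/m
  kT300_eV    = 1.380649e-23 * 300 / 1.602176634e-19
)

#' Thermal energy in kcal/mol
#' @param T temperature in K
#' @return kT in kcal/mol (e.g. 0.5962 at 300 K)
#' @export
kT_kcal <- function(T = 300) PHYS$R_kcal * T

#' RT ln 10 in kcal/mol
#'
#' The free energy of one pH unit; 1.3726 kcal/mol (59.52 mV) at 300 K.
#' @param T temperature in K
#' @export
RTln10 <- function(T = 300) PHYS$R_kcal * T * log(10)

#' Nernstian slope in mV per pH unit
#' @param T temperature in K
#' @export
nernst_slope_mV <- function(T = 300) RTln10(T) * PHYS$mV_per_kcal
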