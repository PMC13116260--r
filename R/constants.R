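# Physical constants (SI, CODATA 2018) and unit conversion factors used
# throughout. Internal computations are SI; user-facing interfaces use the
# field's customary units (angstrom, eV, THz, ps).

.const <- list(
  kB      = 1.380649e-23,        # Boltzmann constant, J/K
  h       = 6.62607015e-34,      # Planck constant, J s
  hbar    = 1.054571817e-34,     # reduced Planck constant, J s
  e       = 1.602176634e-19,     # elementary charge, C
  ke      = 8.9875517873681764e9, # Coulomb constant 1/(4 pi eps0), N m^2/C^2
  amu     = 1.66053906660e-27,   # atomic mass unit, kg
  eV      = 1.602176634e-19,     # J per eV
  ang     = 1e-10,               # m per angstrom
  THz     = 1e12                 # Hz per THz
)

# Ca-40 (2+) defaults: mass of the bare isotope; the two missing electron
# masses are negligible at this precision.
.ca_mass   <- 39.962590863 * .const$amu   # 6.636e-26 kg
.ca_charge <- 2 * .const$e                # +2e = 3.204e-19 C

#' Thermal energy at a temperature
#'
#' @param temperature Temperature in kelvin.
#' @return `kB * T` in joules.
#' @examples
#' kBT(310) / 1.602176634e-19  # ~0.0267 eV
#' @export
kBT <- function(temperature) .const$kB * temperature
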