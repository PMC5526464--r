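# Physical constants used throughout. All magnetic fields in this package are
# expressed as mu0*H in tesla, so mu0 appears only where a field is first
# synthesized (Biot-Savart) and never downstream.

#' Physical constants
#'
#' Named list of the physical constants the package relies on:
#' `mu0` (vacuum permeability, T m/A), `kB` (Boltzmann constant, J/K),
#' `rho_magnetite` (magnetite mass density, kg/m^3) and `fe_mass_fraction`
#' (iron mass fraction of magnetite, 3*55.845/231.533).
#'
#' @return Named list of constants.
#' @export
#' @examples
#' ffl_constants()$mu0
ffl_constants <- function() {
  list(
    mu0 = 4e-7 * pi,
    kB = 1.380649e-23,
    rho_magnetite = 5175,
    fe_mass_fraction = 0.7236
  )
}

.mu0 <- 4e-7 * pi
.kB <- 1.380649e-23
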