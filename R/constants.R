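# Physical constants (SI) and the unit conversions used throughout.
# Convention: SI for lengths/times/energies/velocities inside the engine;
# particle and vesicle diameters are carried in nm at the interface and
# converted here, in one place.

#' Physical constants used by the simulator
#'
#' @returns Named list: `k_B` Boltzmann constant (J/K), `N_A` Avogadro
#'   number (1/mol), `g` standard gravity (m/s^2), `R_gas` molar gas
#'   constant (J/mol/K), `eps_water` permittivity of water at body
#'   temperature (F/m).
#' @export
phys_constants <- function() {
  list(
    k_B = 1.380649e-23,
    N_A = 6.02214076e23,
    g = 9.80665,
    R_gas = 8.314462618,
    # relative permittivity ~74 at 37 C; 78.5 at 25 C. A mid value is used;
    # the Debye screening at physiological ionic strength is insensitive
    # to this at the precision that matters here.
    eps_water = 74 * 8.8541878128e-12
  )
}

# nm -> m
nm_to_m <- function(x) x * 1e-9
m_to_nm <- function(x) x * 1e9

# g/cm^3 (= g/mL) -> ng/nm^3 : 1 g/cm^3 = 1e9 ng / 1e21 nm^3
gcm3_to_ng_nm3 <- function(x) x * 1e-12
# g/cm^3 -> kg/m^3
gcm3_to_kgm3 <- function(x) x * 1000

# mass (ng) of a sphere of diameter d_nm (nm) and density rho (g/cm^3)
sphere_mass_ng <- function(d_nm, rho_gcm3) {
  gcm3_to_ng_nm3(rho_gcm3) * (pi / 6) * d_nm^3
}

# diameter (nm) of a sphere of mass m_ng (ng) and density rho (g/cm^3)
sphere_diameter_nm <- function(m_ng, rho_gcm3) {
  (6 * m_ng / (pi * gcm3_to_ng_nm3(rho_gcm3)))^(1 / 3)
}

# surface area (nm^2) of a sphere of diameter d_nm
sphere_area_nm2 <- function(d_nm) pi * d_nm^2

#' Debye screening length of an electrolyte
#'
#' kappa^-1 = 0.304 / sqrt(I) nm with I in mol/L (1:1 electrolyte at
#' ambient-to-body temperature, the usual colloid-science approximation).
#'
#' @param ionic_strength_mM ionic strength in mM.
#' @returns Debye length in m.
#' @export
debye_length <- function(ionic_strength_mM) {
  stopifnot(ionic_strength_mM > 0)
  nm_to_m(0.304 / sqrt(ionic_strength_mM / 1000))
}

# mass of one 4-nm bilayer patch per nm^2, in ng/nm^2
bilayer_areal_mass <- function(thickness_nm, density_gcm3) {
  thickness_nm * gcm3_to_ng_nm3(density_gcm3)
}
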