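# Reference property tables: surfactant proteins, the ENM catalogue, and
# alveolar-lining-fluid properties. These are the published physical
# property values the simulator is parameterised with; everything is
# overridable through the configuration.

#' Surfactant protein properties
#'
#' Physical and kinetic properties of the four pulmonary surfactant
#' proteins. SP-B and SP-C are the surface-active proteins, closely
#' associated with surfactant lipids; SP-A and SP-D are collectins of the
#' innate immune system.
#'
#' Columns: molecular weight (kDa), molecule length (nm), headgroup
#' diameter (nm), density (g/cm^3), concentration in alveolar fluid
#' (ug/mL), diffusivity (m^2/s), and the corona-kinetics baselines:
#' `ka0` (m/s; the adsorption-velocity coefficient entering the
#' adsorption-limited attempt rate 2 R^2 Co ka'), `kd0` (dimensionless
#' desorption baseline; the net rate ka' = ka/kd is what the attempt uses),
#' and the power-law coverage coefficients `beta_a`, `n_a`, `beta_d`,
#' `n_d` (ka = ka0 (1 + beta_a theta^n_a), kd likewise).
#'
#' The baselines encode the surface-active/collectin split: SP-B/SP-C get a
#' large `ka0` so their adsorption runs at the diffusion limit, with strong
#' lipid enhancement (`beta_a` = 4); SP-A/SP-D adsorb reaction-limited with
#' a small `ka0` and weak enhancement.
#'
#' @returns A tibble with one row per protein species.
#' @export
surfactant_proteins <- function() {
  tibble::tibble(
    species = c("SP-A", "SP-B", "SP-C", "SP-D"),
    class = c("collectin", "surface_active", "surface_active", "collectin"),
    mol_wt_kDa = c(32, 9, 3.8, 42),
    length_nm = c(20, 7.9, 3.4, 92),
    headgroup_diameter_nm = c(20, 3, 2, 92),
    density_gcm3 = c(1.41, 1.48, 1.5, 1.4),
    conc_ug_mL = c(132.5, 19.93, 19.93, 39.64),
    diffusivity_m2s = c(0.093e-9, 0.5474e-9, 0.796e-9, 0.0206e-9),
    ka0 = c(5e-10, 1e-2, 1e-2, 5e-10),
    kd0 = c(1, 1, 1, 1),
    beta_a = c(0.25, 4, 4, 0.25),
    n_a = c(1, 1, 1, 1),
    beta_d = c(0.5, 0.5, 0.5, 0.5),
    n_d = c(1, 1, 1, 1)
  )
}

# number concentration (molecules/m^3) from a mass concentration in ug/mL
protein_number_conc <- function(conc_ug_mL, mol_wt_kDa) {
  # ug/mL = g/L = 1000 g/m^3 ; mol wt in g/mol = 1000 * kDa
  conc_ug_mL * 1e-3 / (mol_wt_kDa * 1000) * 1000 * phys_constants()$N_A
}

#' Catalogue of nanoparticle specifications
#'
#' The six particle types used across the calibration and in vivo
#' scenarios: the 20-nm citrate silver particle of the seven-day
#' lipid-solution study (`L20`), the 600-nm uncoated silica particle of the
#' one-hour vesicle-adsorption study (`N600`), and the four in vivo silver
#' particles (20/110 nm, citrate/PVP coated).
#'
#' @returns A tibble, one row per specification label.
#' @export
enm_catalog <- function() {
  tibble::tibble(
    enm_spec = c("L20", "N600", "C20", "P20", "C110", "P110"),
    core_material = c("Ag", "SiO2", "Ag", "Ag", "Ag", "Ag"),
    coating = c("citrate", "none", "citrate", "PVP", "citrate", "PVP"),
    diameter_nm = c(20, 600, 20, 20, 110, 110),
    core_density_gcm3 = c(10.49, 2, 10.87, 10.87, 10.49, 10.49),
    core_mol_wt = c(108, 108, 115.3, 115.3, 108.04, 108.04),
    coating_mol_wt = c(258, NA, 258, 10000, 258, 40000),
    zeta_mV = c(-39.2, -25, -44.3, -38.2, -45.2, -31.6),
    # polymer/ligand brush geometry entering the steric repulsion term:
    # chain length L (nm) and surface density nm_ (molecules/nm^2).
    # Short citrate ligands pack densely; 10-kDa PVP is denser per unit
    # area than 40-kDa PVP (fewer, longer chains).
    coating_chain_nm = c(0.5, NA, 0.5, 4, 0.5, 8),
    coating_density_nm2 = c(2, NA, 2, 0.3, 2, 0.1)
  )
}

#' Alveolar lining fluid properties
#'
#' Bulk physical properties of the alveolar lining layer used by the in
#' vivo scenario: fluid density, lipid and protein concentrations,
#' phospholipid density, ionic strength, pH, viscosity and layer thickness.
#'
#' @returns Named list of physical properties (units in names).
#' @export
alveolar_lining_properties <- function() {
  list(
    fluid_density_gcm3 = 1.04,
    lipid_conc_ug_mL = 328,
    protein_conc_ug_mL = 212,
    pl_density_gcm3 = 1.108,
    ionic_strength_mM = 245,
    pH = 7.28,
    viscosity = 8.79e-4,          # kg/(m s)
    thickness_m = 0.2e-6,
    surface_tension_Nm = 0.03,    # ~30 dyn/cm at the functioning interface
    temperature_K = 310.15,
    dissolved_O2_mgL = 8.96
  )
}
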