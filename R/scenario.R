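# Scenario construction: inhaled dose conversion, control volume sizing,
# medium state and the initial particle population.

#' Inhaled particle number dose per unit alveolar surface
#'
#' Converts an airborne mass concentration into the number of particles
#' deposited per square metre of alveolar surface in one breath:
#' `dose = mass_conc * breath_volume / particle_mass * deposition_fraction
#' / alveolar_area`, with the particle mass computed from the labelled
#' monomer diameter and core density.
#'
#' @param mass_conc_mg_m3 Airborne mass concentration (mg/m^3).
#' @param breath_volume_m3 Inhaled volume per breath (m^3).
#' @param diameter_nm Monomer diameter (nm).
#' @param density_gcm3 Core density (g/cm^3).
#' @param deposition_fraction Fraction of inhaled particles deposited in
#'   the alveolar region (dimensionless, from external airway-deposition
#'   modelling).
#' @param alveolar_area_m2 Alveolar air-exchange area (m^2).
#' @returns Deposited particles per m^2 of alveolar surface.
#' @examples
#' # reference exposure: 0.14 mg/m^3 silver, 20-nm monomers, one 0.5-L breath
#' inhaled_number_dose(0.14, 5e-4, 20, 10.49, 0.3, 70)
#' @export
inhaled_number_dose <- function(mass_conc_mg_m3, breath_volume_m3,
                                diameter_nm, density_gcm3,
                                deposition_fraction, alveolar_area_m2) {
  stopifnot(mass_conc_mg_m3 >= 0, breath_volume_m3 > 0,
            density_gcm3 > 0, deposition_fraction >= 0,
            alveolar_area_m2 > 0)
  if (diameter_nm <= 0) stop("diameter must be > 0", call. = FALSE)
  particle_mass_mg <- sphere_mass_ng(diameter_nm, density_gcm3) * 1e-6
  mass_conc_mg_m3 * breath_volume_m3 / particle_mass_mg *
    deposition_fraction / alveolar_area_m2
}

#' Control volume holding N tracked particles at a given areal dose
#'
#' The constant-number scheme tracks `N` particles; the alveolar surface
#' area they correspond to is `N / areal_dose`, and the control volume is
#' that area times the lining-layer thickness.
#'
#' @param N Number of tracked particles.
#' @param areal_dose_m2 Deposited particles per m^2 (see
#'   [inhaled_number_dose()]).
#' @param thickness_m Lining-layer thickness (m).
#' @returns A `control_volume` list: `area_m2`, `thickness_m`, `volume_m3`,
#'   `number_conc_m3`.
#' @export
control_volume_for_N <- function(N, areal_dose_m2, thickness_m) {
  stopifnot(N >= 1, areal_dose_m2 > 0, thickness_m > 0)
  area <- N / areal_dose_m2
  new_control_volume(area, thickness_m, N)
}

new_control_volume <- function(area_m2, thickness_m, N) {
  volume <- area_m2 * thickness_m
  structure(
    list(area_m2 = area_m2, thickness_m = thickness_m,
         volume_m3 = volume, number_conc_m3 = N / volume),
    class = "control_volume"
  )
}

new_medium_state <- function(cfg, cv) {
  prot <- surfactant_proteins()
  # the in vitro calibration media are lipid solutions without
  # surfactant proteins
  prot_conc <- if (cfg$scenario == "invivo_human") prot$conc_ug_mL else
    rep(0, nrow(prot))
  lipid_pool <- if (isTRUE(cfg$lipid_pool_dynamic)) {
    # finite pool: lipid mass available inside the control volume (ng)
    cfg$lipid_conc_ug_mL * 1e3 * cv$volume_m3 * 1e6   # ug/mL = 1e3 ng/mL = 1e9 ng/L
  } else {
    Inf
  }
  structure(list(
    temperature_K = cfg$temperature_K,
    viscosity = cfg$viscosity,
    fluid_density_gcm3 = cfg$fluid_density_gcm3,
    pH = cfg$pH,
    ionic_strength_mM = cfg$ionic_strength_mM,
    dissolved_O2_mgL = cfg$dissolved_O2_mgL,
    surface_tension_Nm = cfg$surface_tension_Nm,
    layer_thickness_m = cfg$layer_thickness_m,
    lipid_conc_ug_mL = cfg$lipid_conc_ug_mL,
    protein_concs = stats::setNames(prot_conc, prot$species),
    lipid_pool_dynamic = isTRUE(cfg$lipid_pool_dynamic),
    lipid_pool_ng = lipid_pool,
    lipid_pool_initial_ng = lipid_pool,
    dissolved_metal_pool_ng = 0
  ), class = "medium_state")
}

# particle-spec fields may be overridden from the config (used by the
# sensitivity analysis among others)
apply_spec_overrides <- function(cfg, spec) {
  for (f in c("zeta_mV", "core_density_gcm3", "core_mol_wt",
              "coating_mol_wt", "coating_chain_nm", "coating_density_nm2")) {
    if (!is.null(cfg[[f]])) spec[[f]] <- cfg[[f]]
  }
  spec
}

# initial particle population: a tibble, one row per tracked particle.
# `weight` is the statistical weight (physical particles represented per
# tracked particle, in the units of the initial control volume).
new_population <- function(cfg, spec) {
  N <- cfg$n_particles
  tibble::tibble(
    id = seq_len(N),
    enm_spec = spec$enm_spec,
    coating = spec$coating,
    core_density_gcm3 = spec$core_density_gcm3,
    core_mol_wt = spec$core_mol_wt,
    d_nm = spec$diameter_nm,
    n_primary = 1L,
    depth_m = 0,
    zeta0_mV = spec$zeta_mV,
    theta = 0,
    pl_mass_ng = 0,
    `SP-A` = 0, `SP-B` = 0, `SP-C` = 0, `SP-D` = 0,
    weight = 1,
    t_entry = 0,
    t_last_pl = NA_real_,
    dissolved = FALSE
  )
}

#' Construct the initial state of a scenario
#'
#' Builds the medium, the N-particle monomer population (all with clean
#' surfaces, theta = 0) and the control volume for a configuration. In the
#' in vivo scenario all particles start at the top of the lining layer
#' (depth 0) and the control volume is sized from the inhaled areal dose;
#' in the in vitro scenarios particles start at depth 0 of the liquid
#' column and the control volume is sized from the suspension mass
#' concentration.
#'
#' @param cfg A [sim_config()].
#' @returns A list: `medium` (medium_state), `population` (tibble),
#'   `cv` (control_volume), `spec` (catalogue row).
#' @export
build_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  spec <- apply_spec_overrides(
    cfg, enm_catalog()[enm_catalog()$enm_spec == cfg$enm_spec, ]
  )
  if (cfg$scenario == "invivo_human") {
    dose <- cfg$areal_dose_m2
    if (is.null(dose)) {
      dose <- inhaled_number_dose(
        cfg$mass_conc_mg_m3, cfg$breath_volume_L * 1e-3,
        spec$diameter_nm, spec$core_density_gcm3,
        cfg$deposition_fraction, cfg$alveolar_area_m2
      )
    }
    cv <- control_volume_for_N(cfg$n_particles, dose, cfg$layer_thickness_m)
  } else {
    particle_mass_mg <- sphere_mass_ng(spec$diameter_nm,
                                       spec$core_density_gcm3) * 1e-6
    number_conc <- cfg$enm_conc_mg_L / particle_mass_mg * 1e3  # per m^3
    volume <- cfg$n_particles / number_conc
    area <- volume / cfg$layer_thickness_m
    cv <- new_control_volume(area, cfg$layer_thickness_m, cfg$n_particles)
    if (!is.null(cfg$av_ap_ratio)) {
      # lipid dose expressed as the vesicle-to-particle surface area
      # ratio Av/Ap (how the one-hour incubation study reports doses)
      area_conc_nm2_m3 <- number_conc * sphere_area_nm2(spec$diameter_nm)
      lipid_ng_m3 <- cfg$av_ap_ratio * area_conc_nm2_m3 *
        bilayer_areal_mass(cfg$bilayer_thickness_nm, cfg$pl_density_gcm3)
      cfg$lipid_conc_ug_mL <- lipid_ng_m3 / 1e9
    }
  }
  medium <- new_medium_state(cfg, cv)
  list(medium = medium, population = new_population(cfg, spec), cv = cv,
       spec = spec)
}
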