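# Shared fixtures: tiny particle rows, media, and short-run configs used
# across the suite. Everything is generated in code.

particle_row <- function(d_nm = 20, theta = 0, zeta0 = -44.3,
                         coating = "citrate", rho = 10.87, weight = 1) {
  tibble::tibble(
    id = 1L, enm_spec = "C20", coating = coating,
    core_density_gcm3 = rho, core_mol_wt = 115.3,
    d_nm = d_nm, n_primary = 1L, depth_m = 0, zeta0_mV = zeta0,
    theta = theta, pl_mass_ng = theta * 4.432e-12 * pi * d_nm^2,
    `SP-A` = 0, `SP-B` = 0, `SP-C` = 0, `SP-D` = 0,
    weight = weight, t_entry = 0, t_last_pl = NA_real_, dissolved = FALSE
  )
}

lining_medium <- function(...) {
  base <- list(
    temperature_K = 310.15, viscosity = 8.79e-4,
    fluid_density_gcm3 = 1.04, pH = 7.28, ionic_strength_mM = 245,
    dissolved_O2_mgL = 8.96, surface_tension_Nm = 0.03,
    layer_thickness_m = 0.2e-6, lipid_conc_ug_mL = 328,
    lipid_pool_dynamic = FALSE, lipid_pool_ng = Inf,
    lipid_pool_initial_ng = Inf, dissolved_metal_pool_ng = 0
  )
  utils::modifyList(base, list(...))
}

citrate_params <- function(eta_s = 2.35) {
  interaction_params(eta_s = eta_s, coating_chain_nm = 0.5,
                     coating_density_nm2 = 2)
}

pvp_params <- function(chain = 4, density = 0.3) {
  interaction_params(eta_s = 10.6, coating_chain_nm = chain,
                     coating_density_nm2 = density)
}

# a fast in vivo config (small N) for engine-level tests
quick_invivo <- function(enm = "C20", seed = 7, ...) {
  sim_config("invivo_human", enm, seed = seed, n_particles = 20,
             n_replicates = 2, ...)
}

# agglomeration-focused condition: equal elevated number concentration
# for every particle spec (areal dose chosen so the merge count over a
# millisecond-scale run is measurable)
agglomeration_test_config <- function(enm, seed = 11, N = 60) {
  sim_config("invivo_human", enm, seed = seed, n_particles = N,
             areal_dose_m2 = 2e12)
}

# protein-incubation condition: particles held in the fluid (no
# immersion drift, thick layer) so the corona builds over tens of
# seconds
protein_incubation_config <- function(enm = "C20", seed = 5, t_end = 50) {
  sim_config("invivo_human", enm, seed = seed, n_particles = 30,
             v_immersion = 0, layer_thickness_m = 1e-3,
             max_time = t_end, stop_fraction = 1e-6)
}
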