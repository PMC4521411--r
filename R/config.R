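# Scenario configuration: defaults per scenario, a validated constructor,
# and a YAML loader. A config is a plain named list with class
# "sim_config" (a control object, not a data frame).

sim_scenarios <- c("leo2013", "nordlund2009", "invivo_human")

# Defaults shared by every scenario. Scenario-specific entries below
# override these; user values override both.
base_defaults <- function() {
  lining <- alveolar_lining_properties()
  list(
    scenario = "invivo_human",
    enm_spec = "C20",
    n_particles = 100,
    seed = 1L,
    n_replicates = 10,
    # lipid-vesicle adsorption
    alpha = 0.004,
    p_diff = 0.001,
    vesicle_diffusivity = 8.7e-10,  # m^2/s, vesicle-encounter diffusivity
    intact_fraction = 0.01,          # metadata: fraction of vesicles that
                                     # stay intact after adsorption
    bilayer_thickness_nm = 4,
    pl_density_gcm3 = lining$pl_density_gcm3,
    # steric/electrostatic interaction
    eta_s = 2.35,
    hamaker_J = 3.7e-20,
    zeta_lipid_mV = -18,
    # transport
    v_immersion = 7.481e-5,          # m/s, in vivo immersion speed
    contact_angle_deg = 20,
    phi_deg = 160,
    # dissolution (first-order oxidative surface law)
    k_diss0 = 4.1e-9,                # ng/(nm^2 s (mg/L O2)) pre-exponential
    Ea_J_mol = 60e3,
    lambda_pH = 0.25,
    coating_diss_multiplier = c(citrate = 1, PVP = 1e-3, none = 1),
    min_diameter_nm = 1,
    # medium
    temperature_K = lining$temperature_K,
    viscosity = lining$viscosity,
    fluid_density_gcm3 = lining$fluid_density_gcm3,
    pH = lining$pH,
    ionic_strength_mM = lining$ionic_strength_mM,
    dissolved_O2_mgL = lining$dissolved_O2_mgL,
    surface_tension_Nm = lining$surface_tension_Nm,
    layer_thickness_m = lining$thickness_m,
    lipid_conc_ug_mL = lining$lipid_conc_ug_mL,
    # dose (in vivo)
    mass_conc_mg_m3 = 0.14,
    breath_volume_L = 0.5,
    deposition_fraction = 0.3,
    alveolar_area_m2 = 70,
    # engine
    stop_fraction = 0.01,
    max_time = 60,
    dt_policy = "slowest",
    sweep_event_budget = 2e4,
    transport_resolution = 20,
    gravity = FALSE,
    lipid_pool_dynamic = FALSE
  )
}

scenario_overrides <- function(scenario) {
  switch(scenario,
    invivo_human = list(enm_spec = "C20"),
    leo2013 = list(
      enm_spec = "L20",
      alpha = 0.004, eta_s = 2.35,
      ionic_strength_mM = 0.1, pH = 7,
      temperature_K = 310.15,
      fluid_density_gcm3 = 1.0,
      viscosity = 8.79e-4,
      system_volume_mL = 4,
      enm_conc_mg_L = 25,
      layer_thickness_m = 0.01,       # liquid depth in the tube
      lipid_conc_ug_mL = 100,         # DPPC supplementation
      vesicle_mean_nm = 100, vesicle_sd_nm = 20,
      gravity = TRUE, lipid_pool_dynamic = TRUE,
      max_time = 7 * 86400, stop_fraction = 1e-9
    ),
    nordlund2009 = list(
      enm_spec = "N600",
      alpha = 0.001, eta_s = 1,
      ionic_strength_mM = 100, pH = 7.4,
      temperature_K = 295.15,
      fluid_density_gcm3 = 1.0,
      viscosity = 9.54e-4,            # water at 22 C
      enm_conc_mg_L = 3000,
      av_ap_ratio = 1,                # vesicle-to-particle surface area
      layer_thickness_m = 0.01,
      vesicle_mean_nm = 100, vesicle_sd_nm = 20,
      gravity = FALSE,                # stirred incubation
      lipid_pool_dynamic = TRUE,
      max_time = 3600, stop_fraction = 1e-9
    ),
    stop(sprintf("unknown scenario '%s'; valid scenarios: %s",
                 scenario, paste(sim_scenarios, collapse = ", ")),
         call. = FALSE)
  )
}

# in vivo zeta/coating parameters come from the ENM catalogue; the PVP
# specs use the stronger steric factor
enm_overrides <- function(enm_spec, scenario) {
  cat_row <- enm_catalog()[enm_catalog()$enm_spec == enm_spec, ]
  if (nrow(cat_row) == 0) {
    stop(sprintf("unknown enm_spec '%s'; valid specs: %s",
                 enm_spec, paste(enm_catalog()$enm_spec, collapse = ", ")),
         call. = FALSE)
  }
  out <- list()
  if (scenario == "invivo_human" && cat_row$coating == "PVP") {
    out$eta_s <- 10.6
  }
  out
}

#' Build a validated simulation configuration
#'
#' Assembles scenario defaults (`leo2013`, `nordlund2009`, `invivo_human`),
#' particle-specification defaults from [enm_catalog()], and any user
#' overrides into a validated configuration object.
#'
#' @param scenario One of `"leo2013"`, `"nordlund2009"`, `"invivo_human"`.
#' @param enm_spec Particle specification label from [enm_catalog()].
#' @param ... Named overrides for any configuration field.
#' @returns A `sim_config` object (named list).
#' @examples
#' cfg <- sim_config("invivo_human", "C20")
#' cfg$alpha      # 0.004
#' cfg$eta_s      # 2.35
#' @export
sim_config <- function(scenario = "invivo_human", enm_spec = NULL, ...) {
  if (!is.character(scenario) || !scenario %in% sim_scenarios) {
    stop(sprintf("unknown scenario '%s'; valid scenarios: %s",
                 as.character(scenario)[1],
                 paste(sim_scenarios, collapse = ", ")), call. = FALSE)
  }
  cfg <- utils::modifyList(base_defaults(), scenario_overrides(scenario))
  cfg$scenario <- scenario
  if (!is.null(enm_spec)) cfg$enm_spec <- enm_spec
  cfg <- utils::modifyList(cfg, enm_overrides(cfg$enm_spec, scenario))
  user <- list(...)
  if (length(user)) {
    unknown <- setdiff(names(user), c(names(cfg), "vesicle_mean_nm",
                                      "vesicle_sd_nm", "system_volume_mL",
                                      "enm_conc_mg_L", "av_ap_ratio",
                                      "zeta_mV", "coating_chain_nm",
                                      "coating_density_nm2",
                                      "core_density_gcm3", "core_mol_wt",
                                      "coating_mol_wt", "areal_dose_m2"))
    if (length(unknown)) {
      stop("unknown config field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg <- utils::modifyList(cfg, user)
  }
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) {
      stop(sprintf("invalid config field '%s': %s", field, msg),
           call. = FALSE)
    }
  }
  chk(cfg$n_particles >= 2, "n_particles", "must be >= 2")
  chk(cfg$stop_fraction > 0 && cfg$stop_fraction < 1, "stop_fraction",
      "must lie in (0, 1)")
  chk(cfg$alpha > 0, "alpha", "must be > 0")
  chk(cfg$eta_s > 0, "eta_s", "must be > 0")
  chk(cfg$p_diff > 0, "p_diff", "must be > 0")
  chk(cfg$pH > 0 && cfg$pH < 14, "pH", "must lie in (0, 14)")
  for (f in c("temperature_K", "viscosity", "fluid_density_gcm3",
              "ionic_strength_mM", "surface_tension_Nm", "layer_thickness_m",
              "max_time")) {
    chk(is.numeric(cfg[[f]]) && cfg[[f]] > 0, f, "must be > 0")
  }
  chk(cfg$deposition_fraction >= 0 && cfg$deposition_fraction <= 1,
      "deposition_fraction", "must lie in [0, 1]")
  chk(cfg$dt_policy %in% c("slowest", "fastest"), "dt_policy",
      "must be 'slowest' or 'fastest'")
  structure(cfg, class = "sim_config")
}

#' Load a simulation configuration from a YAML file
#'
#' The file must provide at least `scenario`; every other key is an
#' override applied on top of the scenario defaults (see [sim_config()]).
#'
#' @param path Path to a YAML configuration file.
#' @returns A validated `sim_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$scenario)) {
    stop("config file must name a 'scenario'", call. = FALSE)
  }
  scenario <- raw$scenario
  enm_spec <- raw$enm_spec
  raw$scenario <- NULL
  raw$enm_spec <- NULL
  do.call(sim_config, c(list(scenario = scenario, enm_spec = enm_spec), raw))
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> scenario=%s enm_spec=%s N=%d seed=%s\n",
              x$scenario, x$enm_spec, x$n_particles, format(x$seed)))
  invisible(x)
}
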