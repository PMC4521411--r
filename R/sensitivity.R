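# Local one-at-a-time sensitivity analysis: each parameter is perturbed
# by a small fraction while all others stay nominal; perturbed and base
# runs share seeds to suppress Monte Carlo noise, indices are averaged
# over iterations and normalised per output by the largest-magnitude
# index.

#' The standard sensitivity parameter set
#'
#' Seventeen parameters in three groups — alveolar-interface properties
#' (fluid density, viscosity, pH, temperature, ionic strength, layer
#' thickness, alveolar area), phospholipid-adsorption parameters
#' (adsorption probability constant, vesicle diffusion-encounter
#' probability, phospholipid density, vesicle diffusivity), and particle
#' properties (core molecular weight, core density, surface zeta
#' potential, coating surface density, coating molecular weight,
#' dissolution rate constant) — mapped to their configuration fields.
#'
#' @returns Named character vector: names are parameter labels, values
#'   the config fields they perturb.
#' @export
sensitivity_parameters <- function() {
  c(
    balf_density = "fluid_density_gcm3",
    balf_viscosity = "viscosity",
    balf_ph = "pH",
    balf_temperature = "temperature_K",
    balf_ionic_strength = "ionic_strength_mM",
    layer_thickness = "layer_thickness_m",
    alveolar_area = "alveolar_area_m2",
    pl_adsorption_alpha = "alpha",
    pl_diffusion_probability = "p_diff",
    pl_density = "pl_density_gcm3",
    pl_vesicle_diffusivity = "vesicle_diffusivity",
    np_mol_wt = "core_mol_wt",
    np_density = "core_density_gcm3",
    np_zeta = "zeta_mV",
    coating_density = "coating_density_nm2",
    coating_mol_wt = "coating_mol_wt",
    reaction_rate_constant = "k_diss0"
  )
}

default_rate_simulator <- function(cfg) {
  run <- run_simulation(cfg)
  rates <- estimate_kinetic_rates(run, require_deposits = FALSE)
  unlist(rates[, c("agglomeration_rate", "transport_rate",
                   "dissolution_rate", "pl_adsorption_rate")])
}

#' Local sensitivity indices of simulator outputs to parameters
#'
#' For each parameter `p` the index is
#' `Si = (V* - V) / (V * delta)`, where `V` is an output at nominal
#' parameters, `V*` the output with `p` scaled by `1 + delta`, and
#' `delta` the fractional perturbation (default 1%). Base and perturbed
#' runs of an iteration share a seed; indices are averaged over
#' `iterations` and normalised per output by the largest `|Si|`, so the
#' most influential parameter of every output has normalised index +/-1.
#'
#' @param cfg Base [sim_config()].
#' @param parameters Named character vector mapping labels to config
#'   fields (default [sensitivity_parameters()]).
#' @param delta Fractional perturbation.
#' @param iterations Replicate pairs to average over (seeds `seed`,
#'   `seed+1`, ...).
#' @param simulator Function `cfg -> named numeric outputs`; defaults to
#'   running the DSMC and returning agglomeration, transport, dissolution
#'   and phospholipid-adsorption rates.
#' @returns Tibble (class `sensitivity_result`): `parameter`, `output`,
#'   `Si`, `Si_normalized`.
#' @export
local_sensitivity <- function(cfg, parameters = sensitivity_parameters(),
                              delta = 0.01, iterations = 10,
                              simulator = default_rate_simulator) {
  stopifnot(delta > 0, iterations >= 1)
  per_iter <- purrr::map(seq_len(iterations), function(it) {
    cfg_b <- cfg
    cfg_b$seed <- cfg$seed + it - 1
    V <- simulator(cfg_b)
    if (any(!is.finite(V)) || any(V == 0)) {
      stop("sensitivity index undefined: a base output is zero or ",
           "non-finite (", paste(names(V)[!is.finite(V) | V == 0],
                                 collapse = ", "), ")", call. = FALSE)
    }
    purrr::imap_dfr(parameters, function(field, label) {
      cfg_p <- cfg_b
      old <- cfg_p[[field]]
      if (is.null(old)) old <- lookup_spec_field(cfg_b, field)
      cfg_p[[field]] <- old * (1 + delta)
      cfg_p <- validate_sim_config(cfg_p)
      Vs <- simulator(cfg_p)
      tibble::tibble(parameter = label, output = names(V),
                     Si = (Vs - V) / (V * delta))
    })
  })
  out <- dplyr::bind_rows(per_iter) |>
    dplyr::group_by(.data$parameter, .data$output) |>
    dplyr::summarise(Si = mean(.data$Si), .groups = "drop") |>
    dplyr::group_by(.data$output) |>
    dplyr::mutate(Si_normalized = .data$Si / max(abs(.data$Si))) |>
    dplyr::ungroup()
  class(out) <- c("sensitivity_result", class(out))
  out
}

# particle-spec fields (zeta, core density, ...) default from the
# catalogue; pull the nominal value so it can be perturbed via the
# config override mechanism
lookup_spec_field <- function(cfg, field) {
  spec <- enm_catalog()[enm_catalog()$enm_spec == cfg$enm_spec, ]
  map <- c(zeta_mV = "zeta_mV", core_density_gcm3 = "core_density_gcm3",
           core_mol_wt = "core_mol_wt", coating_mol_wt = "coating_mol_wt",
           coating_density_nm2 = "coating_density_nm2",
           coating_chain_nm = "coating_chain_nm")
  if (!field %in% names(map)) {
    stop("sensitivity parameter maps to unknown config field: ", field,
         call. = FALSE)
  }
  spec[[map[[field]]]]
}
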