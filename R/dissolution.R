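# Oxidative dissolution of the particle core: a surface-area-limited
# first-order law with Arrhenius temperature dependence, linear dependence
# on dissolved oxygen, exponential pH acceleration, and blocking by the
# adsorbed lipid layer (only the exposed fraction fSA reacts).

#' Oxidative dissolution mass rate of one particle
#'
#' `dm/dt = -k0 exp(-Ea/(R T)) [O2] 10^(lambda (7 - pH)) g(I) c_coat fSA
#'  pi d^2` (ng/s), where `fSA = 1 - theta` is the lipid-free surface
#' fraction, `c_coat` a per-coating multiplier (PVP passivates strongly),
#' and `g(I) = 1` by default. Fully covered particles (`fSA = 0`) do not
#' dissolve.
#'
#' @param enm One-row particle tibble (`d_nm`, `theta`, `coating`).
#' @param medium Medium state (temperature, pH, dissolved O2).
#' @param k_diss0 Pre-exponential rate (ng/(nm^2 s (mg/L O2))).
#' @param Ea_J_mol Activation energy (J/mol).
#' @param lambda_pH pH acceleration per unit below 7.
#' @param coating_multiplier Named vector of per-coating multipliers.
#' @param g_ionic Ionic-strength factor (default 1).
#' @returns Mass loss rate (ng/s), `<= 0`.
#' @export
dissolution_rate <- function(enm, medium, k_diss0 = 4.1e-9,
                             Ea_J_mol = 60e3, lambda_pH = 0.25,
                             coating_multiplier = c(citrate = 1, PVP = 1e-3,
                                                    none = 1),
                             g_ionic = 1) {
  if (any(c(k_diss0, Ea_J_mol, lambda_pH) < 0) || any(coating_multiplier < 0)) {
    stop("dissolution constants must be non-negative", call. = FALSE)
  }
  stopifnot(!enm$dissolved)
  pc <- phys_constants()
  cmult <- coating_multiplier[[enm$coating]]
  fSA <- 1 - enm$theta
  -k_diss0 * exp(-Ea_J_mol / (pc$R_gas * medium$temperature_K)) *
    medium$dissolved_O2_mgL * 10^(lambda_pH * (7 - medium$pH)) *
    g_ionic * cmult * fSA * sphere_area_nm2(enm$d_nm)
}

#' Advance dissolution of one particle over a time step
#'
#' Reduces the core mass by `|dm/dt| * dt` (never below zero), recomputes
#' the diameter from the remaining volume, and credits the released mass
#' to the medium's dissolved-metal pool (weighted by the particle's
#' statistical weight). A particle shrinking below the minimum diameter
#' is marked dissolved and its full remainder credited to the pool.
#'
#' @param enm One-row particle tibble.
#' @param medium Medium state.
#' @param dt Time step (s), > 0.
#' @param min_diameter_nm Complete-dissolution threshold (nm).
#' @param ... Passed to [dissolution_rate()].
#' @returns List `enm`, `medium`.
#' @export
apply_dissolution_step <- function(enm, medium, dt, min_diameter_nm = 1, ...) {
  stopifnot(dt > 0)
  rate <- dissolution_rate(enm, medium, ...)
  m0 <- sphere_mass_ng(enm$d_nm, enm$core_density_gcm3)
  dm <- min(-rate * dt, m0)
  m1 <- m0 - dm
  w <- if ("weight" %in% names(enm)) enm$weight else 1
  d1 <- sphere_diameter_nm(m1, enm$core_density_gcm3)
  if (m1 <= 0 || d1 < min_diameter_nm) {
    medium$dissolved_metal_pool_ng <- medium$dissolved_metal_pool_ng + m0 * w
    enm$dissolved <- TRUE
    enm$d_nm <- 0
  } else {
    medium$dissolved_metal_pool_ng <- medium$dissolved_metal_pool_ng + dm * w
    enm$d_nm <- d1
  }
  list(enm = enm, medium = medium)
}
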