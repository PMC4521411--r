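# Vertical transport through the lining layer: Stokes settling (in
# vitro), surface-tension-driven immersion (in vivo), Brownian
# displacement, and deposition bookkeeping at the bottom of the control
# volume (the alveolar cell surface).

#' Stokes settling velocity
#'
#' `v = (rho_p - rho_f) g d^2 / (18 mu)`, positive downward.
#'
#' @param d_nm Particle diameter (nm).
#' @param rho_p_gcm3,rho_f_gcm3 Particle and fluid densities (g/cm^3).
#' @param viscosity Fluid viscosity (kg/(m s)).
#' @returns Settling velocity (m/s). Vectorised.
#' @export
stokes_settling_velocity <- function(d_nm, rho_p_gcm3, rho_f_gcm3,
                                     viscosity) {
  stopifnot(all(d_nm >= 0), rho_p_gcm3 > 0, rho_f_gcm3 > 0, viscosity > 0)
  pc <- phys_constants()
  (gcm3_to_kgm3(rho_p_gcm3) - gcm3_to_kgm3(rho_f_gcm3)) * pc$g *
    nm_to_m(d_nm)^2 / (18 * viscosity)
}

#' Surface-tension immersion velocity
#'
#' The capillary force pulling a particle through the air-liquid
#' interface, balanced against Stokes drag, gives
#' `v = (gamma / (3 mu)) sin(phi) sin(theta_c + phi)`. The particle
#' radius cancels between the capillary force and the drag, so the
#' velocity is size-independent — all particle types immerse at the same
#' speed. With the literature interface angles (contact angle 20 deg,
#' position angle 160 deg) the product of sines vanishes, so the engine
#' drives in vivo motion with a calibrated immersion-speed constant
#' (`v_immersion`) and this mechanistic formula is kept as the documented
#' force balance.
#'
#' @param gamma_Nm Surface tension (N/m).
#' @param viscosity Fluid viscosity (kg/(m s)).
#' @param contact_angle_deg Contact angle at the particle surface (deg).
#' @param phi_deg Angle between the contact line and the particle axis
#'   (deg).
#' @returns Immersion velocity (m/s).
#' @export
surface_tension_velocity <- function(gamma_Nm, viscosity,
                                     contact_angle_deg = 20,
                                     phi_deg = 160) {
  stopifnot(gamma_Nm >= 0, viscosity > 0)
  to_rad <- pi / 180
  (gamma_Nm / (3 * viscosity)) * sin(phi_deg * to_rad) *
    sin((contact_angle_deg + phi_deg) * to_rad)
}

#' Brownian vertical displacement over a time step
#'
#' Stokes-Einstein diffusion `D = kT / (3 pi mu d)`; the displacement is
#' `Normal(0, sqrt(2 D dt))`.
#'
#' @param d_nm Particle diameter (nm). Vectorised.
#' @param viscosity Fluid viscosity (kg/(m s)).
#' @param T_K Temperature (K).
#' @param dt Time step (s), >= 0.
#' @param n Number of draws (defaults to `length(d_nm)`).
#' @returns Displacements (m).
#' @export
brownian_displacement <- function(d_nm, viscosity, T_K, dt,
                                  n = length(d_nm)) {
  stopifnot(dt >= 0, all(d_nm > 0))
  if (dt == 0) return(rep(0, n))
  D <- stokes_einstein_diffusivity(d_nm, viscosity, T_K)
  stats::rnorm(n, 0, sqrt(2 * D * dt))
}

stokes_einstein_diffusivity <- function(d_nm, viscosity, T_K) {
  phys_constants()$k_B * T_K / (3 * pi * viscosity * nm_to_m(d_nm))
}

#' Advance particle depths and collect deposited particles
#'
#' Moves every suspended particle by drift (immersion speed in vivo,
#' Stokes settling in vitro, zero when stirred) plus a Brownian kick,
#' reflecting at the air-liquid interface (depth 0). Particles reaching
#' the bottom of the layer are moved, with their full adsorbed state, to
#' the deposited inventory — the dosimetry output — and are not mutated
#' afterwards.
#'
#' @param population Particle tibble.
#' @param medium Medium state (`layer_thickness_m`, viscosity,
#'   temperature).
#' @param dt Time step (s).
#' @param mode `"in_vivo"` or `"in_vitro"`.
#' @param v_immersion In vivo immersion speed (m/s).
#' @param gravity Logical; apply Stokes settling (in vitro, unstirred).
#' @param t Current time (s), stamped on deposits.
#' @returns List `population` (still suspended), `deposited` (tibble with
#'   `t_deposit`).
#' @export
advance_and_deposit <- function(population, medium, dt, mode,
                                v_immersion = 0, gravity = FALSE, t = 0) {
  alive <- !population$dissolved
  if (!any(alive)) {
    empty <- population[0, ]
    empty$t_deposit <- numeric(0)
    return(list(population = population, deposited = empty))
  }
  d <- population$d_nm[alive]
  v <- if (mode == "in_vivo") {
    rep(v_immersion, length(d))
  } else if (gravity) {
    stokes_settling_velocity(d, population$core_density_gcm3[alive],
                             medium$fluid_density_gcm3, medium$viscosity)
  } else {
    rep(0, length(d))
  }
  dz <- v * dt + brownian_displacement(d, medium$viscosity,
                                       medium$temperature_K, dt)
  depth <- population$depth_m[alive] + dz
  depth <- abs(depth)                      # reflect at the interface
  thickness <- medium$layer_thickness_m
  depth <- pmin(depth, thickness)
  population$depth_m[alive] <- depth
  hit <- rep(FALSE, nrow(population))
  hit[alive] <- depth >= thickness
  deposited <- population[hit, ]
  deposited$t_deposit <- rep(t, nrow(deposited))
  list(population = population[!hit, ], deposited = deposited)
}
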