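# Surfactant-protein corona kinetics: coverage-dependent net
# adsorption/desorption rates, regime selection (adsorption- vs
# diffusion-limited), attempt probabilities with their time steps, and the
# footprint-capped adsorption attempt.

#' Coverage-dependent protein adsorption/desorption rates
#'
#' Power-law modulation of the baseline rates by the particle's lipid
#' coverage theta:
#' `ka = ka0 (1 + beta_a theta^n_a)`, `kd = kd0 (1 + beta_d theta^n_d)`,
#' and the net rate `ka' = ka / kd` that folds desorption into a single
#' effective adsorption coefficient.
#'
#' @param sp One row of [surfactant_proteins()] (or any list with `ka0`,
#'   `kd0`, `beta_a`, `n_a`, `beta_d`, `n_d`).
#' @param theta Lipid surface coverage in \[0, 1\].
#' @returns List `ka`, `kd`, `ka_net`.
#' @export
coverage_dependent_rates <- function(sp, theta) {
  stopifnot(all(theta >= 0), all(theta <= 1))
  if (any(sp$kd0 == 0)) stop("kd0 = 0: net rate undefined", call. = FALSE)
  ka <- sp$ka0 * (1 + sp$beta_a * theta^sp$n_a)
  kd <- sp$kd0 * (1 + sp$beta_d * theta^sp$n_d)
  list(ka = ka, kd = kd, ka_net = ka / kd)
}

#' Select the limiting protein-adsorption regime
#'
#' Computes the adsorption-limited attempt rate `2 R^2 Co ka'` and the
#' diffusion-limited attempt rate `2 R^2 Co sqrt(D / (pi t))` and returns
#' the regime of the *smaller* one — the slower process limits the
#' kinetics. At `t = 0` the diffusive flux is unbounded, so the
#' adsorption-limited branch is used (ties also resolve to
#' adsorption-limited, deterministically).
#'
#' @param sp One row of [surfactant_proteins()].
#' @param theta Lipid coverage of the particle.
#' @param t System time (s).
#' @returns `"adsorption_limited"` or `"diffusion_limited"`.
#' @export
select_regime <- function(sp, theta, t) {
  stopifnot(t >= 0)
  if (t == 0) return("adsorption_limited")
  p_ads <- protein_attempt_probability(sp, theta, t, "adsorption_limited")$p_ad
  p_dif <- protein_attempt_probability(sp, theta, t, "diffusion_limited")$p_ad
  if (p_ads <= p_dif) "adsorption_limited" else "diffusion_limited"
}

#' Protein adsorption attempt rate and its time step
#'
#' Under the adsorption-limited regime the per-particle attempt rate is
#' `PAd = 2 R^2 Co ka'` (1/s; `R` headgroup radius in m, `Co` number
#' concentration in molecules/m^3, `ka'` in m/s) with time step
#' `dt = 1 / PAd`. Under the diffusion-limited regime
#' `PAd = 2 R^2 Co sqrt(D / (pi t))` with
#' `dt = sqrt(pi t / D) / (Co A)`, `A` the headgroup area (m^2). The
#' product `PAd * dt_attempt`, capped at 1, is the acceptance probability
#' of one attempt spanning `dt_attempt` seconds.
#'
#' @param sp One row of [surfactant_proteins()].
#' @param theta Lipid coverage.
#' @param t System time (s).
#' @param regime `"adsorption_limited"` or `"diffusion_limited"` (see
#'   [select_regime()]).
#' @returns List `p_ad` (attempt rate, 1/s) and `dt` (associated time
#'   step, s).
#' @export
protein_attempt_probability <- function(sp, theta, t, regime) {
  R_m <- nm_to_m(sp$headgroup_diameter_nm / 2)
  A_m2 <- pi * R_m^2
  Co <- protein_number_conc(sp$conc_ug_mL, sp$mol_wt_kDa)
  if (!all(is.finite(c(R_m, Co, theta, t)))) {
    stop("non-finite protein attempt inputs", call. = FALSE)
  }
  if (regime == "adsorption_limited") {
    ka_net <- coverage_dependent_rates(sp, theta)$ka_net
    p <- 2 * R_m^2 * Co * ka_net
    list(p_ad = p, dt = ifelse(p > 0, 1 / p, Inf))
  } else if (regime == "diffusion_limited") {
    stopifnot(t > 0)
    p <- 2 * R_m^2 * Co * sqrt(sp$diffusivity_m2s / (pi * t))
    dt <- sqrt(pi * t / sp$diffusivity_m2s) / (Co * A_m2)
    list(p_ad = p, dt = dt)
  } else {
    stop("unknown regime: ", regime, call. = FALSE)
  }
}

# maximum number of molecules of each species that fit on a particle:
# total adsorbed footprint (sum over species of count * headgroup area)
# may not exceed the particle surface area.
protein_footprint_nm2 <- function(sp) pi * (sp$headgroup_diameter_nm / 2)^2

#' One protein-adsorption attempt on one particle
#'
#' Selects the limiting regime, computes the attempt rate, and accepts
#' with probability `min(PAd * dt, 1)` over the attempt interval `dt`.
#' An accepted molecule is added only if its headgroup footprint still
#' fits within the particle's unoccupied surface area.
#'
#' @param enm One-row particle tibble (protein count columns named by
#'   species).
#' @param sp One row of [surfactant_proteins()].
#' @param t System time (s).
#' @param dt Attempt interval (s); defaults to the regime's own time step.
#' @returns List `enm` (updated), `accepted`, `regime`.
#' @export
attempt_protein_adsorption <- function(enm, sp, t, dt = NULL) {
  stopifnot(!enm$dissolved)
  regime <- select_regime(sp, enm$theta, t)
  pp <- protein_attempt_probability(sp, enm$theta, t, regime)
  if (is.null(dt)) dt <- pp$dt
  q <- min(pp$p_ad * dt, 1)
  accepted <- FALSE
  if (q > 0 && stats::runif(1) < q) {
    if (protein_area_free_nm2(enm) >= protein_footprint_nm2(sp)) {
      enm[[sp$species]] <- enm[[sp$species]] + 1
      accepted <- TRUE
    }
  }
  list(enm = enm, accepted = accepted, regime = regime)
}

# unoccupied surface area (nm^2) given current protein counts
protein_area_free_nm2 <- function(enm) {
  prot <- surfactant_proteins()
  occupied <- 0
  for (i in seq_len(nrow(prot))) {
    occupied <- occupied +
      enm[[prot$species[i]]] * protein_footprint_nm2(prot[i, ])
  }
  sphere_area_nm2(enm$d_nm) - occupied
}
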