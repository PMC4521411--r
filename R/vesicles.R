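# Surfactant lipid-vesicle adsorption: vesicle size mixture, the
# exponential size-ratio adsorption probability, the collision/acceptance
# rule, and rupture of adsorbed vesicles into 4-nm bilayer patches.

#' Surfactant vesicle population model
#'
#' Describes the lipid vesicle mixture the particles encounter. The in
#' vivo alveolar fluid is modelled as a two-class mixture of small
#' unilamellar vesicles (SUVs, 20-50 nm) and large unilamellar vesicles
#' (LUVs, 50-500 nm); each class is a normal distribution whose 5th/95th
#' percentiles sit at the class size limits. Mixture weights default to
#' the lavage-fluid light (43%) and heavy (48%) fraction masses,
#' renormalised over the two vesicle classes (the 9% ultra-heavy
#' aggregate fraction is excluded as non-adsorbing). In vitro scenarios
#' use a single extruded-formulation class (`mean_nm` +/- `sd_nm`).
#'
#' @param suv_range,luv_range Class size limits in nm (5th/95th
#'   percentiles of each normal).
#' @param suv_weight,luv_weight Unnormalised mixture weights.
#' @param mean_nm,sd_nm If supplied, a single normal class (commercial
#'   formulation) replaces the two-class mixture.
#' @param lipid_density_gcm3 Phospholipid density.
#' @param bilayer_thickness_nm Thickness of a supported bilayer patch.
#' @param intact_fraction Fraction of adsorbed vesicles expected to stay
#'   intact (carried as metadata; all adsorbed vesicles are treated as
#'   rupturing).
#' @returns A `vesicle_population` list with per-class means and sds.
#' @export
vesicle_population <- function(suv_range = c(20, 50), luv_range = c(50, 500),
                               suv_weight = 43, luv_weight = 48,
                               mean_nm = NULL, sd_nm = NULL,
                               lipid_density_gcm3 = 1.108,
                               bilayer_thickness_nm = 4,
                               intact_fraction = 0.01) {
  z95 <- stats::qnorm(0.95)
  if (!is.null(mean_nm)) {
    classes <- tibble::tibble(
      class = "formulation", prob = 1, mean_nm = mean_nm, sd_nm = sd_nm
    )
  } else {
    w <- c(suv_weight, luv_weight) / (suv_weight + luv_weight)
    classes <- tibble::tibble(
      class = c("SUV", "LUV"),
      prob = w,
      mean_nm = c(mean(suv_range), mean(luv_range)),
      sd_nm = c(diff(suv_range) / 2, diff(luv_range) / 2) / z95
    )
  }
  structure(list(classes = classes,
                 lipid_density_gcm3 = lipid_density_gcm3,
                 bilayer_thickness_nm = bilayer_thickness_nm,
                 intact_fraction = intact_fraction),
            class = "vesicle_population")
}

vesicle_population_for <- function(cfg) {
  if (cfg$scenario == "invivo_human") {
    vesicle_population(lipid_density_gcm3 = cfg$pl_density_gcm3,
                       bilayer_thickness_nm = cfg$bilayer_thickness_nm,
                       intact_fraction = cfg$intact_fraction)
  } else {
    vesicle_population(mean_nm = cfg$vesicle_mean_nm,
                       sd_nm = cfg$vesicle_sd_nm,
                       lipid_density_gcm3 = cfg$pl_density_gcm3,
                       bilayer_thickness_nm = cfg$bilayer_thickness_nm,
                       intact_fraction = cfg$intact_fraction)
  }
}

#' Draw vesicle diameters from the population mixture
#'
#' Picks a class by mixture weight, then draws from that class's normal;
#' non-positive draws are resampled.
#'
#' @param pop A [vesicle_population()].
#' @param n Number of draws.
#' @param class Optional fixed class name (e.g. `"SUV"`) to bypass the
#'   mixture step.
#' @returns Numeric vector of diameters (nm), strictly positive.
#' @export
sample_vesicle_diameter <- function(pop, n = 1, class = NULL) {
  cl <- pop$classes
  if (!is.null(class)) {
    idx <- rep(match(class, cl$class), n)
    if (anyNA(idx)) stop("unknown vesicle class: ", class, call. = FALSE)
  } else {
    idx <- sample.int(nrow(cl), n, replace = TRUE, prob = cl$prob)
  }
  d <- stats::rnorm(n, cl$mean_nm[idx], cl$sd_nm[idx])
  while (any(bad <- d <= 0)) {
    d[bad] <- stats::rnorm(sum(bad), cl$mean_nm[idx[bad]], cl$sd_nm[idx[bad]])
  }
  d
}

#' Vesicle-on-particle adsorption probability
#'
#' `Pad = exp(-alpha * dves^2 / (fSA^2 * dENM^2))`; a fully covered
#' particle (`fSA = 0`) cannot adsorb, so `Pad = 0` there. Large vesicles
#' on small, already partly covered particles adsorb with low
#' probability.
#'
#' @param dves_nm Vesicle diameter (nm).
#' @param dENM_nm Particle diameter (nm).
#' @param fSA Exposed (lipid-free) surface fraction, in \[0, 1\].
#' @param alpha Adsorption probability constant (scenario-calibrated).
#' @returns Probability in \[0, 1\]; vectorised.
#' @export
vesicle_adsorption_probability <- function(dves_nm, dENM_nm, fSA, alpha) {
  if (any(alpha < 0)) stop("alpha must be non-negative", call. = FALSE)
  stopifnot(all(dENM_nm > 0), all(fSA >= 0), all(fSA <= 1))
  out <- ifelse(fSA == 0, 0,
                exp(-alpha * dves_nm^2 / (fSA^2 * dENM_nm^2)))
  out
}

#' Rupture an adsorbed vesicle into a bilayer patch
#'
#' An adsorbed vesicle ruptures and spreads a bilayer patch whose area is
#' the vesicle's outer surface area `pi * dves^2`. The particle's coverage
#' increases by the patch-to-particle area ratio, capped at full coverage;
#' the adsorbed phospholipid mass grows by the covered area times the
#' 4-nm bilayer areal mass. Patch area beyond full coverage is discarded
#' (returned to the pool in the finite-pool scenarios).
#'
#' @param enm One-row particle tibble (needs `d_nm`, `theta`,
#'   `pl_mass_ng`).
#' @param dves_nm Diameter of the ruptured vesicle (nm).
#' @param pop A [vesicle_population()] (bilayer thickness and lipid
#'   density).
#' @returns The updated one-row particle tibble, with attribute
#'   `delta_mass_ng` (lipid mass actually deposited).
#' @export
apply_rupture_coverage <- function(enm, dves_nm, pop) {
  d_theta <- min(dves_nm^2 / enm$d_nm^2, 1 - enm$theta)
  covered_nm2 <- d_theta * sphere_area_nm2(enm$d_nm)
  dm <- covered_nm2 * bilayer_areal_mass(pop$bilayer_thickness_nm,
                                         pop$lipid_density_gcm3)
  enm$theta <- enm$theta + d_theta
  enm$pl_mass_ng <- enm$pl_mass_ng + dm
  attr(enm, "delta_mass_ng") <- dm
  enm
}

#' One Monte Carlo vesicle-adsorption attempt on one particle
#'
#' Draws a vesicle from the population, computes the adsorption
#' probability, and accepts when a uniform draw falls below
#' `Pad / (Pad + P_diff)` (the diffusion-encounter competition rule). On
#' success the vesicle ruptures ([apply_rupture_coverage()]) and, when
#' the medium has a finite (dynamic) lipid pool, the pool is debited by
#' the deposited mass; an exhausted pool makes the attempt a no-op.
#'
#' @param enm One-row particle tibble.
#' @param pop A [vesicle_population()].
#' @param medium A medium state (needs `lipid_pool_dynamic`,
#'   `lipid_pool_ng`).
#' @param alpha,p_diff Adsorption and diffusion-encounter probability
#'   constants.
#' @returns List: `enm` (possibly updated), `medium`, `accepted` flag,
#'   `dves_nm`, `delta_mass_ng` (weighted by the particle's statistical
#'   weight when debiting the pool).
#' @export
attempt_vesicle_adsorption <- function(enm, pop, medium, alpha, p_diff) {
  stopifnot(!enm$dissolved)
  dves <- sample_vesicle_diameter(pop, 1)
  pad <- vesicle_adsorption_probability(dves, enm$d_nm, 1 - enm$theta, alpha)
  accepted <- FALSE
  dm <- 0
  if (pad > 0 && stats::runif(1) < pad / (pad + p_diff)) {
    if (!medium$lipid_pool_dynamic || medium$lipid_pool_ng > 0) {
      enm2 <- apply_rupture_coverage(enm, dves, pop)
      dm <- attr(enm2, "delta_mass_ng")
      w <- if ("weight" %in% names(enm)) enm$weight else 1
      if (medium$lipid_pool_dynamic) {
        if (medium$lipid_pool_ng >= dm * w) {
          medium$lipid_pool_ng <- medium$lipid_pool_ng - dm * w
          enm <- enm2
          accepted <- TRUE
        } else {
          dm <- 0   # pool cannot cover the patch: no-op event
        }
      } else {
        enm <- enm2
        accepted <- TRUE
      }
    }
  }
  list(enm = enm, medium = medium, accepted = accepted, dves_nm = dves,
       delta_mass_ng = dm)
}

# characteristic time between vesicle-encounter attempts for one particle:
# the time a vesicle needs to diffuse across the mean inter-vesicle
# spacing, tau = l^2 / (6 D), l = C_ves^(-1/3). Size-independent, matching
# the constant (size-independent) encounter probability P_diff.
vesicle_attempt_timescale <- function(pop, lipid_conc_ug_mL, D_ves) {
  conc <- vesicle_number_conc(pop, lipid_conc_ug_mL)
  if (conc <= 0) return(Inf)
  l <- conc^(-1 / 3)
  l^2 / (6 * D_ves)
}

# vesicle number concentration (per m^3) given the lipid mass
# concentration: vesicles are thin bilayer shells, mass = pi d^2 t rho
vesicle_number_conc <- function(pop, lipid_conc_ug_mL) {
  cl <- pop$classes
  mean_d2_nm2 <- cl$mean_nm^2 + cl$sd_nm^2
  shell_mass_ng <- pi * mean_d2_nm2 *
    bilayer_areal_mass(pop$bilayer_thickness_nm, pop$lipid_density_gcm3)
  conc_ng_m3 <- lipid_conc_ug_mL * 1e9       # 1 ug/mL = 1e9 ng/m^3
  sum(cl$prob * conc_ng_m3 / shell_mass_ng)
}
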