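# Pairwise Brownian agglomeration: effective (coverage-weighted) zeta
# potential, DLVO van der Waals + electrostatic energies, polymer-brush
# steric repulsion, the Fuchs stability ratio, the modified Smoluchowski
# collision kernel, and the constant-number merge step.

#' Interaction parameters for a coated particle pair
#'
#' Bundles the constants of the pair interaction energy: Hamaker constant,
#' the zeta potential of a fully lipid-coated surface, the steric factor
#' eta_S, and the coating-brush geometry (chain length `L`, surface
#' density `nm_`, mean inter-chain spacing `s = 1/sqrt(nm_)`).
#'
#' @param hamaker_J Hamaker constant (J).
#' @param zeta_lipid_mV Zeta potential of a lipid-covered surface (mV).
#' @param eta_s Steric factor scaling the brush repulsion.
#' @param coating_chain_nm Brush chain length L (nm); `NA` for uncoated.
#' @param coating_density_nm2 Chains per nm^2; `NA` for uncoated.
#' @returns An `interaction_params` list (with `s_nm` filled in).
#' @export
interaction_params <- function(hamaker_J = 3.7e-20, zeta_lipid_mV = -18,
                               eta_s = 2.35, coating_chain_nm = NA,
                               coating_density_nm2 = NA) {
  stopifnot(hamaker_J > 0, eta_s >= 0)
  s_nm <- if (is.na(coating_density_nm2)) NA else 1 / sqrt(coating_density_nm2)
  structure(list(hamaker_J = hamaker_J, zeta_lipid_mV = zeta_lipid_mV,
                 eta_s = eta_s, coating_chain_nm = coating_chain_nm,
                 coating_density_nm2 = coating_density_nm2, s_nm = s_nm),
            class = "interaction_params")
}

interaction_params_for <- function(cfg, spec) {
  interaction_params(
    hamaker_J = cfg$hamaker_J, zeta_lipid_mV = cfg$zeta_lipid_mV,
    eta_s = cfg$eta_s,
    coating_chain_nm = spec$coating_chain_nm,
    coating_density_nm2 = spec$coating_density_nm2
  )
}

#' Effective zeta potential of a partly lipid-coated particle
#'
#' Linear mixing by surface coverage: `zeta = zeta_L * theta +
#' zeta_0 * (1 - theta)`.
#'
#' @param zeta0_mV Bare-particle zeta potential (mV).
#' @param zeta_lipid_mV Fully lipid-coated zeta potential (mV).
#' @param theta Lipid coverage in \[0, 1\]. Vectorised.
#' @returns Effective zeta potential (mV).
#' @export
effective_zeta <- function(zeta0_mV, zeta_lipid_mV, theta) {
  stopifnot(all(theta >= 0), all(theta <= 1))
  zeta_lipid_mV * theta + zeta0_mV * (1 - theta)
}

#' Steric brush repulsion energy between two coated surfaces
#'
#' `Est = eta_S * kT * (nm_ L / s) * ((2L/d)^2.25 - (d/2L)^0.75)` for
#' surface separations `d < 2L` (overlapping brushes), zero otherwise.
#' The prefactor is evaluated with the surface density in chains/nm^2 and
#' `L`, `s` in nm, giving a dimensionless multiple of kT.
#'
#' @param d_nm Surface separation (nm). Vectorised.
#' @param params An [interaction_params()].
#' @param T_K Temperature (K).
#' @returns Repulsive energy (J), non-negative for `d <= 2L`.
#' @export
steric_repulsion_energy <- function(d_nm, params, T_K) {
  stopifnot(all(d_nm > 0))
  L <- params$coating_chain_nm
  s <- params$s_nm
  if (is.na(L) || is.na(s) || L <= 0 || s <= 0) {
    stop("steric energy needs positive chain length and spacing",
         call. = FALSE)
  }
  kT <- phys_constants()$k_B * T_K
  pref <- params$eta_s * kT * params$coating_density_nm2 * L / s
  est <- pref * ((2 * L / d_nm)^2.25 - (d_nm / (2 * L))^0.75)
  ifelse(d_nm < 2 * L, est, 0)
}

# Hamaker sphere-sphere van der Waals energy (J), h surface separation (m)
vdw_energy <- function(h_m, R1_m, R2_m, A_H) {
  x <- h_m^2 + 2 * (R1_m + R2_m) * h_m
  y <- x + 4 * R1_m * R2_m
  -(A_H / 6) * (2 * R1_m * R2_m / x + 2 * R1_m * R2_m / y + log(x / y))
}

# linearised double-layer repulsion, equal-potential HHF form generalised
# to dissimilar spheres/potentials (J); psi in volts, h in m
electrostatic_energy <- function(h_m, R1_m, R2_m, psi1_V, psi2_V, kappa_m) {
  eps <- phys_constants()$eps_water
  Reff <- R1_m * R2_m / (R1_m + R2_m)
  e1 <- exp(-h_m / kappa_m)
  pi * eps * Reff * ((psi1_V + psi2_V)^2 * log(1 + e1) +
                     (psi1_V - psi2_V)^2 * log(pmax(1 - e1, 1e-300)))
}

# total pair interaction energy V(h) in J; h in m
pair_energy <- function(h_m, enm_i, enm_j, medium, params) {
  R1 <- nm_to_m(enm_i$d_nm / 2)
  R2 <- nm_to_m(enm_j$d_nm / 2)
  z1 <- effective_zeta(enm_i$zeta0_mV, params$zeta_lipid_mV, enm_i$theta) / 1000
  z2 <- effective_zeta(enm_j$zeta0_mV, params$zeta_lipid_mV, enm_j$theta) / 1000
  kappa <- debye_length(medium$ionic_strength_mM)
  v <- vdw_energy(h_m, R1, R2, params$hamaker_J) +
    electrostatic_energy(h_m, R1, R2, z1, z2, kappa)
  coated <- !is.na(params$coating_chain_nm) && params$coating_chain_nm > 0 &&
    !is.na(params$s_nm) && params$s_nm > 0 && params$eta_s > 0
  if (coated) {
    v <- v + steric_repulsion_energy(m_to_nm(h_m), params, medium$temperature_K)
  }
  v
}

#' Fuchs stability ratio of a particle pair
#'
#' Retardation of Brownian coagulation by the pair energy
#' `V(h) = V_vdW + V_elec + E_st`. The deepest attractive well of `V` is
#' the capture state (the primary minimum for bare DLVO pairs; the
#' brush-contact secondary minimum for coated pairs, whose steric wall
#' diverges at contact). Coagulation then means diffusing over the
#' outermost barrier into that well, retarded by the Fuchs factor
#' `W = (R1+R2) * integral_{h_b}^{inf} exp(V/kT) / (h + R1 + R2)^2 dh`
#' taken from the barrier crest `h_b` outward. Shallow wells do not hold
#' a pair against thermal motion, so the barrier factor is divided by
#' the thermal capture efficiency `eps = 1 - exp(-|V_min|/kT)`: a deep
#' primary or secondary minimum captures every arriving pair
#' (`eps -> 1`), a vanishing well re-disperses almost all of them
#' (`W -> Inf`). A pair with a qualifying well and no positive outer
#' barrier coagulates at the diffusion limit (`W = 1`); with no
#' attractive minimum at all the pair is sterically stable (`W = 1e30`).
#'
#' @param enm_i,enm_j One-row particle tibbles (`d_nm`, `zeta0_mV`,
#'   `theta`).
#' @param medium Medium state (temperature, ionic strength).
#' @param params An [interaction_params()].
#' @returns Stability ratio `W >= 1` (capped at 1e30).
#' @export
stability_ratio <- function(enm_i, enm_j, medium, params) {
  kT <- phys_constants()$k_B * medium$temperature_K
  Rs <- nm_to_m((enm_i$d_nm + enm_j$d_nm) / 2)
  vfun <- function(h) pair_energy(h, enm_i, enm_j, medium, params)
  h_grid <- 10^seq(log10(1e-12), log10(1e-6), length.out = 280)
  v_grid <- vapply(h_grid, vfun, numeric(1)) / kT
  if (!any(is.finite(v_grid))) stop("non-finite pair energy", call. = FALSE)
  v_grid[!is.finite(v_grid) & v_grid > 0] <- 1e6
  i_min <- which.min(v_grid)
  if (v_grid[i_min] >= 0) return(1e30)   # no attractive minimum at all
  eps_capture <- 1 - exp(-abs(v_grid[i_min]))
  if (eps_capture <= 1e-30) return(1e30)
  # outermost barrier beyond the well
  outer <- v_grid[i_min:length(v_grid)]
  if (max(outer) <= 0) return(min(max(1 / eps_capture, 1), 1e30))
  i_rel <- which.max(outer)
  i_max <- i_min + i_rel - 1
  lo <- h_grid[max(i_max - 1, 1)]
  hi <- h_grid[min(i_max + 1, length(h_grid))]
  crest <- stats::optimize(function(h) vfun(h) / kT, c(lo, hi),
                           maximum = TRUE)
  h_b <- crest$maximum
  if (crest$objective <= 0) return(min(max(1 / eps_capture, 1), 1e30))
  if (crest$objective > 690) return(1e30)  # exp() overflow guard
  # substitute u = 1/(h + Rs): finite interval, bounded integrand
  integrand_u <- function(u) {
    h <- 1 / u - Rs
    exp(pmin(vapply(h, vfun, numeric(1)) / kT, 690))
  }
  w <- tryCatch(
    Rs * stats::integrate(integrand_u, 0, 1 / (h_b + Rs), rel.tol = 1e-6,
                          stop.on.error = TRUE)$value,
    error = function(e) {
      stop("Fuchs integral failed to converge (barrier ",
           format(crest$objective, digits = 3), " kT at h = ",
           format(h_b, digits = 3), " m): ", conditionMessage(e),
           call. = FALSE)
    }
  )
  min(max(w / eps_capture, 1), 1e30)
}

#' Modified Smoluchowski Brownian collision kernel
#'
#' `beta_ij = (2 kT / 3 mu) * (d_i + d_j)^2 / (d_i d_j) / W`. Symmetric in
#' the pair; the equal-size barrierless limit is `8 kT / 3 mu`.
#'
#' @param d_i_nm,d_j_nm Particle diameters (nm).
#' @param W Stability ratio (>= 1).
#' @param viscosity Medium viscosity (kg/(m s)).
#' @param T_K Temperature (K).
#' @returns Collision kernel (m^3/s). Vectorised.
#' @export
brownian_kernel <- function(d_i_nm, d_j_nm, W, viscosity, T_K) {
  stopifnot(all(d_i_nm > 0), all(d_j_nm > 0), all(W >= 1))
  kT <- phys_constants()$k_B * T_K
  (2 * kT / (3 * viscosity)) * (d_i_nm + d_j_nm)^2 / (d_i_nm * d_j_nm) / W
}

# merge two rows (equal statistical weight) into one volume-equivalent
# sphere; theta is the area-weighted mean, protein counts and lipid mass
# add, depth is core-mass-weighted.
merge_rows <- function(pi_, pj_) {
  stopifnot(isTRUE(all.equal(pi_$weight, pj_$weight)))
  out <- pi_
  vol_i <- pi_$d_nm^3
  vol_j <- pj_$d_nm^3
  a_i <- sphere_area_nm2(pi_$d_nm)
  a_j <- sphere_area_nm2(pj_$d_nm)
  m_i <- sphere_mass_ng(pi_$d_nm, pi_$core_density_gcm3)
  m_j <- sphere_mass_ng(pj_$d_nm, pj_$core_density_gcm3)
  out$d_nm <- (vol_i + vol_j)^(1 / 3)
  out$n_primary <- pi_$n_primary + pj_$n_primary
  out$theta <- (pi_$theta * a_i + pj_$theta * a_j) / (a_i + a_j)
  out$pl_mass_ng <- pi_$pl_mass_ng + pj_$pl_mass_ng
  for (spc in surfactant_proteins()$species) {
    out[[spc]] <- pi_[[spc]] + pj_[[spc]]
  }
  out$depth_m <- (pi_$depth_m * m_i + pj_$depth_m * m_j) / (m_i + m_j)
  out$zeta0_mV <- (pi_$zeta0_mV * a_i + pj_$zeta0_mV * a_j) / (a_i + a_j)
  out$t_last_pl <- suppressWarnings(max(pi_$t_last_pl, pj_$t_last_pl,
                                        na.rm = TRUE))
  if (!is.finite(out$t_last_pl)) out$t_last_pl <- NA_real_
  out
}

#' One constant-number agglomeration attempt
#'
#' Selects a random pair, accepts with probability `beta_ij / beta_max`
#' (majorant rejection sampling), and on acceptance merges the pair into
#' one volume-equivalent sphere. The tracked particle count stays at N:
#' if the pair carries unequal statistical weights the heavier partner is
#' split first (its residual weight stays behind as a separate row), and
#' a merge of equal-weight partners is followed by halving a random
#' survivor's weight into two rows. Total solid volume, adsorbed masses
#' and protein counts are conserved exactly; the represented number
#' concentration drops by one particle's weight.
#'
#' @param population Particle tibble.
#' @param medium Medium state.
#' @param params An [interaction_params()].
#' @param beta_max Majorant kernel value (m^3/s); attempts with
#'   `beta_ij > beta_max` error.
#' @param w_cache Optional environment memoising stability ratios.
#' @returns List `population`, `merged` flag, `pair` (selected ids).
#' @export
dsmc_agglomeration_attempt <- function(population, medium, params,
                                       beta_max, w_cache = NULL) {
  alive <- which(!population$dissolved)
  if (length(alive) < 2) {
    return(list(population = population, merged = FALSE, pair = NULL))
  }
  pick <- sample(alive, 2)
  pi_ <- population[pick[1], ]
  pj_ <- population[pick[2], ]
  W <- cached_stability_ratio(pi_, pj_, medium, params, w_cache)
  beta <- brownian_kernel(pi_$d_nm, pj_$d_nm, W, medium$viscosity,
                          medium$temperature_K)
  if (beta > beta_max * (1 + 1e-9)) {
    stop("majorant kernel exceeded: beta_ij > beta_max", call. = FALSE)
  }
  if (stats::runif(1) >= beta / beta_max) {
    return(list(population = population, merged = FALSE, pair = pick))
  }
  population <- merge_and_rebalance(population, pick[1], pick[2])
  list(population = population, merged = TRUE, pair = pick)
}

# weight-exact constant-number merge bookkeeping
merge_and_rebalance <- function(population, i, j) {
  wi <- population$weight[i]
  wj <- population$weight[j]
  if (!isTRUE(all.equal(wi, wj))) {
    # split the heavier partner so the merging pair has equal weight
    heavy <- if (wi > wj) i else j
    w_light <- min(wi, wj)
    resid <- population[heavy, ]
    resid$weight <- population$weight[heavy] - w_light
    population$weight[heavy] <- w_light
    merged <- merge_rows(transform_weight(population[i, ], w_light),
                         transform_weight(population[j, ], w_light))
    population[i, ] <- merged
    population <- population[-j, ]
    population <- dplyr::bind_rows(population, resid)
  } else {
    merged <- merge_rows(population[i, ], population[j, ])
    population[i, ] <- merged
    population <- population[-j, ]
    # restore N by halving a random survivor's weight into two rows
    k <- sample.int(nrow(population), 1)
    population$weight[k] <- population$weight[k] / 2
    dup <- population[k, ]
    population <- dplyr::bind_rows(population, dup)
  }
  population$id <- seq_len(nrow(population))
  population
}

transform_weight <- function(row, w) {
  row$weight <- w
  row
}

cached_stability_ratio <- function(pi_, pj_, medium, params, w_cache) {
  if (is.null(w_cache)) return(stability_ratio(pi_, pj_, medium, params))
  key <- paste(signif(sort(c(pi_$d_nm, pj_$d_nm)), 3),
               signif(c(pi_$theta, pj_$theta), 2), collapse = "|")
  if (!is.null(w_cache[[key]])) return(w_cache[[key]])
  w <- stability_ratio(pi_, pj_, medium, params)
  w_cache[[key]] <- w
  w
}
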