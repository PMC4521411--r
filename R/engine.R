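# The constant-number DSMC orchestrator. Each sweep: choose a time step
# from the per-process timescales, fire agglomeration / transport /
# vesicle-adsorption / protein-adsorption / dissolution on the tracked
# population, restore the tracked count N by weight-splitting, and record
# the trajectory. Statistical weights make the constant-number
# bookkeeping mass-exact: a removal (deposition, complete dissolution)
# or merge lowers the total weight (the represented concentration) while
# row splits keep exactly N rows.
#
# Internally the population lives in plain atomic vectors (the sweep loop
# is hot); the module operations on tibble rows remain the reference
# semantics and the agglomeration stage runs on the tibble form directly.

#' Choose the sweep time step from per-process timescales
#'
#' `policy = "slowest"` (default, following the stepping rule of the
#' scheme) returns the largest finite timescale; `"fastest"` the
#' smallest. Faster processes then fire `dt / tau` events within the
#' sweep, so no process is starved.
#'
#' @param process_timescales Named numeric vector/list of characteristic
#'   times (s); `Inf` marks an inactive process.
#' @param policy `"slowest"` or `"fastest"`.
#' @returns Time step (s).
#' @export
advance_time <- function(process_timescales, policy = "slowest") {
  tau <- unlist(process_timescales)
  tau <- tau[is.finite(tau) & tau > 0]
  if (length(tau) == 0) {
    stop("all process timescales are infinite", call. = FALSE)
  }
  switch(policy,
         slowest = max(tau),
         fastest = min(tau),
         stop("unknown dt policy: ", policy, call. = FALSE))
}

#' Re-establish the control volume for the constant tracked number
#'
#' After removals the surviving statistical weight `sum(w)` represents a
#' lower physical concentration `n = n0 * sum(w) / N0`; the control
#' volume is resized so the tracked rows again correspond one-to-one to
#' physical particles: `V = n_tracked / n`. With no removals the volume
#' is unchanged.
#'
#' @param population Particle tibble (uses `weight`).
#' @param cv A control volume; `initial_number_conc`/`n_tracked0` record
#'   the reference state (filled from the current state on first use).
#' @returns Updated `control_volume`.
#' @export
resize_control_volume <- function(population, cv) {
  if (is.null(cv$initial_number_conc)) {
    cv$initial_number_conc <- cv$number_conc_m3
    cv$n_tracked0 <- round(cv$number_conc_m3 * cv$volume_m3)
  }
  w_sum <- sum(population$weight)
  if (w_sum <= 0) stop("population extinct: no surviving weight",
                       call. = FALSE)
  n_phys <- cv$initial_number_conc * w_sum / cv$n_tracked0
  volume <- length(population$weight) / n_phys
  out <- cv
  out$volume_m3 <- volume
  out$area_m2 <- volume / cv$thickness_m
  out$number_conc_m3 <- n_phys
  out
}

#' Stop rule of a run
#'
#' Stops when the represented concentration has fallen to
#' `stop_fraction` of its initial value, or when `max_time` is reached
#' (flagged as truncated).
#'
#' @param state List with `t` (s) and `conc_ratio` (current/initial
#'   concentration).
#' @param config A [sim_config()].
#' @returns Logical; attribute `"reason"` is `"stop_fraction"`,
#'   `"max_time"` or `""`.
#' @export
check_stop <- function(state, config) {
  if (state$conc_ratio <= config$stop_fraction) {
    return(structure(TRUE, reason = "stop_fraction"))
  }
  if (state$t >= config$max_time) {
    return(structure(TRUE, reason = "max_time"))
  }
  structure(FALSE, reason = "")
}

# ---- internal vector-state representation -----------------------------

PROTEIN_COLS <- c("SP-A", "SP-B", "SP-C", "SP-D")

pop_to_state <- function(pop) {
  list(
    d = pop$d_nm, np = pop$n_primary, depth = pop$depth_m,
    theta = pop$theta, pl = pop$pl_mass_ng,
    P = as.matrix(pop[, PROTEIN_COLS]),
    w = pop$weight, zeta0 = pop$zeta0_mV,
    tlp = pop$t_last_pl,
    rho = pop$core_density_gcm3,
    coating = pop$coating[1], enm_spec = pop$enm_spec[1],
    core_mol_wt = pop$core_mol_wt[1]
  )
}

state_to_pop <- function(st) {
  n <- length(st$d)
  out <- tibble::tibble(
    id = seq_len(n), enm_spec = st$enm_spec, coating = st$coating,
    core_density_gcm3 = st$rho, core_mol_wt = st$core_mol_wt,
    d_nm = st$d, n_primary = st$np, depth_m = st$depth,
    zeta0_mV = st$zeta0, theta = st$theta, pl_mass_ng = st$pl,
    `SP-A` = st$P[, 1], `SP-B` = st$P[, 2], `SP-C` = st$P[, 3],
    `SP-D` = st$P[, 4],
    weight = st$w, t_entry = 0, t_last_pl = st$tlp, dissolved = FALSE
  )
  out
}

state_subset <- function(st, keep) {
  st$d <- st$d[keep]; st$np <- st$np[keep]; st$depth <- st$depth[keep]
  st$theta <- st$theta[keep]; st$pl <- st$pl[keep]
  st$P <- st$P[keep, , drop = FALSE]
  st$w <- st$w[keep]; st$zeta0 <- st$zeta0[keep]; st$tlp <- st$tlp[keep]
  st$rho <- st$rho[keep]
  st
}

# split k random survivors' weights in half, restoring the tracked count
state_split_weights <- function(st, k) {
  for (i in seq_len(k)) {
    j <- sample.int(length(st$d), 1)
    st$w[j] <- st$w[j] / 2
    st$d <- c(st$d, st$d[j]); st$np <- c(st$np, st$np[j])
    st$depth <- c(st$depth, st$depth[j])
    st$theta <- c(st$theta, st$theta[j]); st$pl <- c(st$pl, st$pl[j])
    st$P <- rbind(st$P, st$P[j, ])
    st$w <- c(st$w, st$w[j]); st$zeta0 <- c(st$zeta0, st$zeta0[j])
    st$tlp <- c(st$tlp, st$tlp[j]); st$rho <- c(st$rho, st$rho[j])
  }
  st
}

#' Run one DSMC simulation
#'
#' Executes the constant-number loop for a configuration: per sweep the
#' process modules (agglomeration, transport, lipid-vesicle adsorption,
#' protein adsorption, dissolution) fire on the tracked population, time
#' advances per the dt policy (bounded by the transport resolution and a
#' per-sweep event budget), the control volume is re-established for the
#' constant tracked number, and the state is recorded. The run stops when
#' the represented concentration falls to `stop_fraction` of its initial
#' value or at `max_time` (truncated, `stop_reason = "max_time"`).
#'
#' @param cfg A [sim_config()].
#' @returns An `alveosim_run` object: `trajectory` (tibble of per-sweep
#'   summaries), `deposited` (dosimetry inventory with arrival times and
#'   full adsorbed state), `population` (still suspended), `medium`,
#'   `cv`, `config`, `stop_reason`, `event_counts`, and conserved-mass
#'   bookkeeping (`initial_core_mass_ng`).
#' @export
run_simulation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  scen <- build_scenario(cfg)
  medium <- scen$medium
  cv <- scen$cv
  cv$initial_number_conc <- cv$number_conc_m3
  cv$n_tracked0 <- cfg$n_particles
  st <- pop_to_state(scen$population)
  pop0_weight <- sum(st$w)
  initial_mass <- sum(st$w * sphere_mass_ng(st$d, st$rho))
  vpop <- vesicle_population_for(cfg)
  params <- interaction_params_for(cfg, scen$spec)
  prot <- if (cfg$scenario == "invivo_human") surfactant_proteins() else
    surfactant_proteins()[0, ]
  mode <- if (cfg$scenario == "invivo_human") "in_vivo" else "in_vitro"
  tau_ves_base <- vesicle_attempt_timescale(vpop, medium$lipid_conc_ug_mL,
                                            cfg$vesicle_diffusivity)
  m_areal <- bilayer_areal_mass(vpop$bilayer_thickness_nm,
                                vpop$lipid_density_gcm3)
  k_diss_eff <- cfg$k_diss0 *
    exp(-cfg$Ea_J_mol / (phys_constants()$R_gas * medium$temperature_K)) *
    medium$dissolved_O2_mgL * 10^(cfg$lambda_pH * (7 - medium$pH)) *
    cfg$coating_diss_multiplier[[st$coating]]
  w_cache <- new.env(parent = emptyenv())
  dep <- list()   # deposited snapshots
  t <- 0
  counts <- c(vesicle_attempts = 0, vesicle_accepts = 0, merges = 0,
              deposits = 0, fully_dissolved = 0, protein_arrivals = 0)
  traj <- list(record_state(t, st, dep, medium, cv, pop0_weight,
                            initial_mass))
  stop_reason <- "max_time"
  repeat {
    uncoated <- any(st$theta < 1 - 1e-12)
    pool_open <- !medium$lipid_pool_dynamic ||
      medium$lipid_pool_ng > 1e-3 * medium$lipid_pool_initial_ng
    # --- per-process characteristic timescales -------------------------
    tau <- c(
      vesicle = if (uncoated && pool_open) tau_ves_base else Inf,
      protein = protein_timescale(prot, st, t),
      dissolution = dissolution_timescale(st, k_diss_eff),
      transport = transport_timescale(st, medium, cfg, mode)
    )
    dt <- tryCatch(advance_time(tau, cfg$dt_policy),
                   error = function(e) cfg$max_time - t)
    # numerical bounds: resolve transport, respect the event budget,
    # never overshoot the horizon
    dt <- min(dt, tau[["transport"]], cfg$max_time - t)
    rate_sum <- event_rate_sum(st, medium, tau, cv)
    if (is.finite(rate_sum) && rate_sum > 0) {
      dt <- min(dt, cfg$sweep_event_budget / rate_sum)
    }
    if (dt <= 0) break
    # --- agglomeration (event-driven pairwise coagulation) -------------
    agg <- agglomeration_stage_state(st, medium, cv, params, dt, t,
                                     w_cache)
    st <- agg$state
    counts["merges"] <- counts["merges"] + agg$merges
    # --- transport and deposition --------------------------------------
    n <- length(st$d)
    v <- if (mode == "in_vivo") {
      rep(cfg$v_immersion, n)
    } else if (isTRUE(cfg$gravity)) {
      stokes_settling_velocity(st$d, st$rho, medium$fluid_density_gcm3,
                               medium$viscosity)
    } else {
      rep(0, n)
    }
    depth <- abs(st$depth + v * dt +
                   brownian_displacement(st$d, medium$viscosity,
                                         medium$temperature_K, dt))
    hit <- depth >= medium$layer_thickness_m
    st$depth <- pmin(depth, medium$layer_thickness_m)
    if (any(hit)) {
      snap <- state_subset(st, hit)
      dep[[length(dep) + 1]] <- c(snap, list(t_dep = rep(t + dt, sum(hit))))
      counts["deposits"] <- counts["deposits"] + sum(hit)
      st <- state_subset(st, !hit)
    }
    if (length(st$d) == 0) {
      stop_reason <- "all_deposited"
      t <- t + dt
      traj[[length(traj) + 1]] <- record_state(t, st, dep, medium, cv,
                                               pop0_weight, initial_mass)
      break
    }
    # --- lipid vesicle adsorption --------------------------------------
    if (is.finite(tau[["vesicle"]])) {
      ves <- vesicle_stage_state(st, vpop, medium, cfg, tau_ves_base,
                                 m_areal, t, dt)
      st <- ves$state
      medium <- ves$medium
      counts["vesicle_attempts"] <- counts["vesicle_attempts"] + ves$attempts
      counts["vesicle_accepts"] <- counts["vesicle_accepts"] + ves$accepts
    }
    # --- protein adsorption --------------------------------------------
    if (nrow(prot) > 0) {
      pr <- protein_stage_state(st, prot, t, dt)
      st <- pr$state
      counts["protein_arrivals"] <- counts["protein_arrivals"] + pr$arrivals
    }
    # --- dissolution ----------------------------------------------------
    if (k_diss_eff > 0) {
      m0 <- sphere_mass_ng(st$d, st$rho)
      dm <- pmin(k_diss_eff * (1 - st$theta) * sphere_area_nm2(st$d) * dt,
                 m0)
      m1 <- m0 - dm
      d1 <- sphere_diameter_nm(m1, st$rho)
      gone <- m1 <= 0 | d1 < cfg$min_diameter_nm
      medium$dissolved_metal_pool_ng <- medium$dissolved_metal_pool_ng +
        sum(st$w * ifelse(gone, m0, dm))
      st$d <- ifelse(gone, 0, d1)
      if (any(gone)) {
        counts["fully_dissolved"] <- counts["fully_dissolved"] + sum(gone)
        st <- state_subset(st, !gone)
      }
    }
    if (length(st$d) == 0) {
      stop_reason <- "population_extinct"
      t <- t + dt
      traj[[length(traj) + 1]] <- record_state(t, st, dep, medium, cv,
                                               pop0_weight, initial_mass)
      break
    }
    # --- constant-number rebalance and CV resize ------------------------
    n_removed <- cfg$n_particles - length(st$d)
    if (n_removed > 0) st <- state_split_weights(st, n_removed)
    cv <- resize_control_volume(list(weight = st$w), cv)
    t <- t + dt
    traj[[length(traj) + 1]] <- record_state(t, st, dep, medium, cv,
                                             pop0_weight, initial_mass)
    stp <- check_stop(list(t = t, conc_ratio = sum(st$w) / pop0_weight),
                      cfg)
    if (stp) {
      stop_reason <- attr(stp, "reason")
      break
    }
  }
  deposited <- deposited_tibble(dep, st)
  structure(list(
    trajectory = dplyr::bind_rows(traj),
    deposited = deposited,
    population = state_to_pop(st),
    medium = medium,
    cv = cv,
    config = cfg,
    seed = cfg$seed,
    stop_reason = stop_reason,
    truncated = identical(stop_reason, "max_time"),
    event_counts = counts,
    initial_core_mass_ng = initial_mass,
    initial_weight = pop0_weight
  ), class = "alveosim_run")
}

deposited_tibble <- function(dep, st_template) {
  if (length(dep) == 0) {
    out <- state_to_pop(state_subset(st_template, integer(0)))
    out$t_deposit <- numeric(0)
    return(out)
  }
  chunks <- lapply(dep, function(snap) {
    td <- snap$t_dep
    snap$t_dep <- NULL
    out <- state_to_pop(snap)
    out$t_deposit <- td
    out
  })
  out <- dplyr::bind_rows(chunks)
  out$id <- seq_len(nrow(out)) + 1e6   # ids disjoint from suspended rows
  out
}

# ---- per-sweep stages (vector state) ----------------------------------

vesicle_stage_state <- function(st, vpop, medium, cfg, tau_ves, m_areal,
                                t, dt) {
  attempts <- 0L
  accepts <- 0L
  eligible <- which(st$theta < 1 - 1e-12)
  if (length(eligible) == 0 || medium$lipid_pool_ng <= 0) {
    return(list(state = st, medium = medium, attempts = 0L, accepts = 0L))
  }
  k <- stats::rpois(length(eligible), dt / tau_ves)
  pool_dyn <- medium$lipid_pool_dynamic
  for (m in seq_along(eligible)) {
    if (k[m] == 0) next
    i <- eligible[m]
    # conditional on k events in the sweep, event times are iid uniform
    times <- sort(stats::runif(k[m], t, t + dt))
    for (tt in times) {
      if (st$theta[i] >= 1 - 1e-12 || medium$lipid_pool_ng <= 0) break
      dves <- sample_vesicle_diameter(vpop, 1)
      pad <- vesicle_adsorption_probability(dves, st$d[i], 1 - st$theta[i],
                                            cfg$alpha)
      attempts <- attempts + 1L
      if (pad > 0 && stats::runif(1) < pad / (pad + cfg$p_diff)) {
        d_theta <- min(dves^2 / st$d[i]^2, 1 - st$theta[i])
        dm <- d_theta * sphere_area_nm2(st$d[i]) * m_areal
        if (pool_dyn && medium$lipid_pool_ng < dm * st$w[i]) next
        if (pool_dyn) {
          medium$lipid_pool_ng <- medium$lipid_pool_ng - dm * st$w[i]
        }
        st$theta[i] <- st$theta[i] + d_theta
        st$pl[i] <- st$pl[i] + dm
        st$tlp[i] <- tt
        accepts <- accepts + 1L
      }
    }
  }
  list(state = st, medium = medium, attempts = attempts, accepts = accepts)
}

protein_stage_state <- function(st, prot, t, dt) {
  arrivals_total <- 0L
  feet <- vapply(seq_len(nrow(prot)),
                 function(s) protein_footprint_nm2(prot[s, ]), numeric(1))
  free <- sphere_area_nm2(st$d) - drop(st$P %*% feet)
  t_mid <- t + dt / 2
  for (s in seq_len(nrow(prot))) {
    sp <- prot[s, ]
    lambda <- protein_arrival_intensity(sp, st$theta, t, dt, t_mid)
    n_new <- stats::rpois(length(st$d), lambda)
    max_add <- pmax(floor(free / feet[s]), 0)
    n_new <- pmin(n_new, max_add)
    st$P[, s] <- st$P[, s] + n_new
    free <- free - n_new * feet[s]
    arrivals_total <- arrivals_total + sum(n_new)
  }
  list(state = st, arrivals = arrivals_total)
}

# expected arrivals on one particle over [t, t+dt] for one species;
# regime chosen by the slower (smaller) attempt intensity
protein_arrival_intensity <- function(sp, theta, t, dt, t_mid) {
  p_ads <- protein_attempt_probability(sp, theta, t_mid,
                                       "adsorption_limited")$p_ad
  R_m <- nm_to_m(sp$headgroup_diameter_nm / 2)
  Co <- protein_number_conc(sp$conc_ug_mL, sp$mol_wt_kDa)
  # exact time integral of the decaying diffusive flux over the sweep
  diff_int <- 2 * R_m^2 * Co * sqrt(sp$diffusivity_m2s / pi) *
    2 * (sqrt(t + dt) - sqrt(t))
  pmin(p_ads * dt, diff_int)
}

# Exact event-driven agglomeration within a sweep: the pairwise rate
# lambda = sum_ij beta_ij / V drives an inner Gillespie loop; each event
# merges a pair drawn with probability proportional to beta_ij. V is
# re-established after every merge (the represented concentration drops),
# so coagulation self-limits. Statistically this realises the same
# pairwise kernel process as majorant rejection sampling
# ([dsmc_agglomeration_attempt()]) without wasting rejected draws.
agglomeration_stage_state <- function(st, medium, cv, params, dt, t,
                                      w_cache) {
  n <- length(st$d)
  if (n < 2) return(list(state = st, merges = 0L))
  state_volume <- function(st) {
    length(st$d) / (cv$initial_number_conc * sum(st$w) / cv$n_tracked0)
  }
  # screen with the barrierless upper bound before paying for W
  kernel_ub <- brownian_kernel(min(st$d), max(st$d), 1, medium$viscosity,
                               medium$temperature_K)
  if (0.5 * n * (n - 1) * kernel_ub / state_volume(st) * dt < 1e-3) {
    return(list(state = st, merges = 0L))
  }
  merges <- 0L
  t_ev <- t
  t_end <- t + dt
  max_merges <- 10L * n
  repeat {
    pr <- pair_rates_state(st, medium, params, w_cache)
    lambda <- sum(pr$beta) / state_volume(st)
    if (!is.finite(lambda) || lambda <= 0) break
    t_ev <- t_ev + stats::rexp(1, lambda)
    if (t_ev >= t_end || merges >= max_merges) break
    k <- sample.int(length(pr$beta), 1, prob = pr$beta)
    st <- state_merge(st, pr$i[k], pr$j[k])
    merges <- merges + 1L
  }
  list(state = st, merges = merges)
}

# kernel values for all unordered pairs, stability ratios memoised on
# rounded (sizes, coverages) keys
pair_rates_state <- function(st, medium, params, w_cache) {
  n <- length(st$d)
  ip <- rep.int(seq_len(n - 1), (n - 1):1)
  jp <- sequence((n - 1):1, from = 2:n)
  di <- st$d[ip]; dj <- st$d[jp]
  ti <- st$theta[ip]; tj <- st$theta[jp]
  zi <- st$zeta0[ip]; zj <- st$zeta0[jp]
  key <- paste(pmin(signif(di, 2), signif(dj, 2)),
               pmax(signif(di, 2), signif(dj, 2)),
               round(pmin(ti, tj), 1), round(pmax(ti, tj), 1), sep = "|")
  uk <- unique(key)
  wv <- numeric(length(uk))
  for (m in seq_along(uk)) {
    if (!is.null(w_cache[[uk[m]]])) {
      wv[m] <- w_cache[[uk[m]]]
    } else {
      first <- match(uk[m], key)
      a <- tibble::tibble(d_nm = di[first], theta = ti[first],
                          zeta0_mV = zi[first])
      b <- tibble::tibble(d_nm = dj[first], theta = tj[first],
                          zeta0_mV = zj[first])
      wv[m] <- stability_ratio(a, b, medium, params)
      w_cache[[uk[m]]] <- wv[m]
    }
  }
  W <- wv[match(key, uk)]
  beta <- brownian_kernel(di, dj, W, medium$viscosity,
                          medium$temperature_K)
  list(i = ip, j = jp, beta = beta)
}

# vector-state merge with exact weight bookkeeping (see merge_rows for
# the tibble-row reference semantics)
state_merge <- function(st, i, j) {
  wi <- st$w[i]
  wj <- st$w[j]
  if (!isTRUE(all.equal(wi, wj))) {
    heavy <- if (wi > wj) i else j
    w_light <- min(wi, wj)
    resid <- w_light   # placeholder; append residual copy of `heavy`
    res_w <- st$w[heavy] - w_light
    st$w[heavy] <- w_light
    st <- state_append_copy(st, heavy, res_w)
    st <- state_merge_equal(st, i, j)
  } else {
    st <- state_merge_equal(st, i, j)
    # restore N by halving a random survivor
    k <- sample.int(length(st$d), 1)
    st$w[k] <- st$w[k] / 2
    st <- state_append_copy(st, k, st$w[k])
  }
  st
}

state_append_copy <- function(st, idx, w_new) {
  st$d <- c(st$d, st$d[idx]); st$np <- c(st$np, st$np[idx])
  st$depth <- c(st$depth, st$depth[idx])
  st$theta <- c(st$theta, st$theta[idx]); st$pl <- c(st$pl, st$pl[idx])
  st$P <- rbind(st$P, st$P[idx, ])
  st$w <- c(st$w, w_new); st$zeta0 <- c(st$zeta0, st$zeta0[idx])
  st$tlp <- c(st$tlp, st$tlp[idx]); st$rho <- c(st$rho, st$rho[idx])
  st
}

state_merge_equal <- function(st, i, j) {
  ai <- sphere_area_nm2(st$d[i]); aj <- sphere_area_nm2(st$d[j])
  mi <- sphere_mass_ng(st$d[i], st$rho[i])
  mj <- sphere_mass_ng(st$d[j], st$rho[j])
  st$d[i] <- (st$d[i]^3 + st$d[j]^3)^(1 / 3)
  st$np[i] <- st$np[i] + st$np[j]
  st$theta[i] <- (st$theta[i] * ai + st$theta[j] * aj) / (ai + aj)
  st$pl[i] <- st$pl[i] + st$pl[j]
  st$P[i, ] <- st$P[i, ] + st$P[j, ]
  st$depth[i] <- (st$depth[i] * mi + st$depth[j] * mj) / (mi + mj)
  st$zeta0[i] <- (st$zeta0[i] * ai + st$zeta0[j] * aj) / (ai + aj)
  tl <- suppressWarnings(max(st$tlp[i], st$tlp[j], na.rm = TRUE))
  st$tlp[i] <- if (is.finite(tl)) tl else NA_real_
  state_subset(st, -j)
}

protein_timescale <- function(prot, st, t) {
  if (nrow(prot) == 0) return(Inf)
  th <- stats::median(st$theta)
  taus <- vapply(seq_len(nrow(prot)), function(s) {
    sp <- prot[s, ]
    reg <- select_regime(sp, th, max(t, 1e-12))
    pp <- protein_attempt_probability(sp, th, max(t, 1e-12), reg)
    if (pp$p_ad > 0) 1 / pp$p_ad else Inf
  }, numeric(1))
  min(taus)
}

dissolution_timescale <- function(st, k_diss_eff) {
  if (k_diss_eff <= 0) return(Inf)
  i <- which.max(st$d)
  rate <- k_diss_eff * (1 - st$theta[i]) * sphere_area_nm2(st$d[i])
  if (rate <= 0) return(Inf)
  0.05 * sphere_mass_ng(st$d[i], st$rho[i]) / rate
}

transport_timescale <- function(st, medium, cfg, mode) {
  d <- st$d
  v <- if (mode == "in_vivo") {
    cfg$v_immersion
  } else if (isTRUE(cfg$gravity)) {
    max(stokes_settling_velocity(d, st$rho, medium$fluid_density_gcm3,
                                 medium$viscosity))
  } else {
    0
  }
  Dmax <- max(stokes_einstein_diffusivity(d, medium$viscosity,
                                          medium$temperature_K))
  L <- medium$layer_thickness_m
  t_cross <- min(if (v > 0) L / v else Inf, L^2 / (2 * Dmax))
  t_cross / cfg$transport_resolution
}

# vesicle/protein attempt load per second; agglomeration is event-driven
# (self-limiting) and excluded
event_rate_sum <- function(st, medium, tau, cv) {
  n <- length(st$d)
  r <- 0
  if (is.finite(tau[["vesicle"]])) r <- r + n / tau[["vesicle"]]
  if (is.finite(tau[["protein"]])) r <- r + n / tau[["protein"]]
  r
}

record_state <- function(t, st, dep, medium, cv, w0, m0) {
  n <- length(st$d)
  w <- st$w
  wm <- function(x) if (n > 0) sum(x * w) / sum(w) else NA_real_
  core_mass <- if (n > 0) sum(w * sphere_mass_ng(st$d, st$rho)) else 0
  dep_mass <- 0
  for (snap in dep) {
    dep_mass <- dep_mass + sum(snap$w * sphere_mass_ng(snap$d, snap$rho))
  }
  tibble::tibble(
    time = t,
    n_tracked = n,
    conc_ratio = sum(w) / w0,
    mean_d_nm = wm(st$d),
    mean_theta = wm(st$theta),
    mean_depth_frac = wm(st$depth) / medium$layer_thickness_m,
    `SP-A` = wm(st$P[, 1]), `SP-B` = wm(st$P[, 2]),
    `SP-C` = wm(st$P[, 3]), `SP-D` = wm(st$P[, 4]),
    suspended_core_ng = core_mass,
    deposited_core_ng = dep_mass,
    dissolved_ng = medium$dissolved_metal_pool_ng,
    dissolved_fraction = medium$dissolved_metal_pool_ng / m0,
    pl_mass_ng = if (n > 0) sum(w * st$pl) else 0,
    lipid_pool_ng = medium$lipid_pool_ng,
    cv_volume_m3 = cv$volume_m3,
    cv_area_m2 = cv$area_m2
  )
}

#' @export
print.alveosim_run <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("<alveosim_run> %s/%s  N=%d  seed=%s\n",
              x$config$scenario, x$config$enm_spec,
              x$config$n_particles, format(x$seed)))
  cat(sprintf("  %d sweeps to t = %.4g s (stop: %s)\n",
              nrow(tr) - 1, max(tr$time), x$stop_reason))
  cat(sprintf("  deposited %d rows, dissolved fraction %.3g, mean theta %.3g\n",
              nrow(x$deposited), tr$dissolved_fraction[nrow(tr)],
              tr$mean_theta[nrow(tr)]))
  invisible(x)
}
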