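# Kinetic-rate extraction from a finished run, and replicate averaging.

#' Estimate kinetic rates from one run
#'
#' Computes the per-run summary rates of particle transformation:
#' \describe{
#'   \item{agglomeration_rate}{increase of the population-mean diameter
#'     per unit time over the run (nm/s).}
#'   \item{transport_rate}{lining-layer thickness divided by the
#'     weight-averaged transit (arrival) time of deposited particles
#'     (m/s); particles still suspended at the end are censored and
#'     excluded.}
#'   \item{dissolution_rate}{final dissolved core-mass fraction per unit
#'     time (1/s).}
#'   \item{pl_adsorption_rate}{adsorbed phospholipid mass per unit
#'     particle surface area per unit *active coating time* (ng/nm^2/s):
#'     each particle's window runs from entry to its last adsorption
#'     event; particles that never adsorbed carry no signal and are
#'     excluded. This matches coverage-based accounting with a uniform
#'     4-nm bilayer. The full-residence variant (total mass over total
#'     area-residence product, all particles) is returned as
#'     `pl_adsorption_rate_fullrun`.}
#'   \item{sa_protein_rate, collectin_rate}{adsorbed surface-active
#'     (SP-B + SP-C) and collectin (SP-A + SP-D) protein amounts
#'     (nmol) per unit surface area per unit residence time
#'     (nmol/nm^2/s).}
#' }
#'
#' @param run An `alveosim_run`.
#' @param require_deposits Error when no particle deposited (the
#'   transport rate is undefined there); set `FALSE` to return `NA`.
#' @returns One-row tibble of rates (units in the descriptions above).
#' @export
estimate_kinetic_rates <- function(run, require_deposits = TRUE) {
  stopifnot(inherits(run, "alveosim_run"))
  tr <- run$trajectory
  elapsed <- max(tr$time)
  if (elapsed <= 0) stop("trajectory is trivial (no elapsed time)",
                         call. = FALSE)
  dep <- run$deposited
  final <- dplyr::bind_rows(run$population, dep)
  residence <- c(rep(elapsed, nrow(run$population)),
                 if (nrow(dep) > 0) dep$t_deposit else numeric(0))
  keep <- !final$dissolved & final$d_nm > 0
  final <- final[keep, ]
  residence <- residence[keep]
  w <- final$weight
  # agglomeration: growth of the mean diameter over the run
  mean_d_end <- sum(w * final$d_nm) / sum(w)
  aggl <- (mean_d_end - tr$mean_d_nm[1]) / elapsed
  # transport: thickness over mean transit time of deposited particles
  if (nrow(dep) == 0) {
    if (require_deposits) {
      stop("no deposited particles: transport rate undefined",
           call. = FALSE)
    }
    transport <- NA_real_
  } else {
    transit <- sum(dep$weight * dep$t_deposit) / sum(dep$weight)
    transport <- run$medium$layer_thickness_m / transit
  }
  dissolution <- tr$dissolved_fraction[nrow(tr)] / elapsed
  # phospholipid adsorption per area over the active coating window
  area <- sphere_area_nm2(final$d_nm)
  active <- !is.na(final$t_last_pl) & final$t_last_pl > 0
  pl_rate <- if (any(active)) {
    sum(w[active] * final$pl_mass_ng[active]) /
      sum(w[active] * area[active] * final$t_last_pl[active])
  } else {
    0
  }
  pl_fullrun <- sum(w * final$pl_mass_ng) / sum(w * area * residence)
  nmol <- function(counts) counts / phys_constants()$N_A * 1e9
  denom <- sum(w * area * residence)
  sa <- sum(w * nmol(final$`SP-B` + final$`SP-C`)) / denom
  coll <- sum(w * nmol(final$`SP-A` + final$`SP-D`)) / denom
  tibble::tibble(
    agglomeration_rate = aggl,
    transport_rate = transport,
    dissolution_rate = dissolution,
    pl_adsorption_rate = pl_rate,
    pl_adsorption_rate_fullrun = pl_fullrun,
    sa_protein_rate = sa,
    collectin_rate = coll,
    elapsed_s = elapsed,
    n_deposited = nrow(dep)
  )
}

#' Run replicates and average their kinetic rates
#'
#' Runs the configuration `n_replicates` times (replicate `r` uses seed
#' `seed + r - 1`), estimates the kinetic rates of each run, and returns
#' the per-replicate table together with the across-replicate mean and
#' sample standard deviation of every rate.
#'
#' @param cfg A [sim_config()].
#' @param n_replicates Number of replicates (default from the config).
#' @param require_deposits Passed to [estimate_kinetic_rates()].
#' @returns List: `replicates` (tibble, one row per seed), `summary`
#'   (tibble with `rate`, `mean`, `sd`).
#' @export
average_over_runs <- function(cfg, n_replicates = cfg$n_replicates,
                              require_deposits = TRUE) {
  stopifnot(n_replicates >= 1)
  reps <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r - 1
    run <- run_simulation(cfg_r)
    out <- estimate_kinetic_rates(run, require_deposits = require_deposits)
    out$seed <- cfg_r$seed
    out
  })
  rate_cols <- c("agglomeration_rate", "transport_rate", "dissolution_rate",
                 "pl_adsorption_rate", "pl_adsorption_rate_fullrun",
                 "sa_protein_rate", "collectin_rate")
  summary <- tidyr::pivot_longer(reps[rate_cols], dplyr::everything(),
                                 names_to = "rate") |>
    dplyr::group_by(.data$rate) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  list(replicates = reps, summary = summary)
}
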