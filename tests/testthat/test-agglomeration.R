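# Zeta mixing, steric brush energy, stability ratio, Brownian kernel and
# the constant-number merge.

test_that("effective zeta is the coverage-weighted mix", {
  expect_equal(effective_zeta(-32.5, -18, 0), -32.5)
  expect_equal(effective_zeta(-32.5, -18, 1), -18)
  expect_equal(effective_zeta(-32.5, -18, 0.5), -25.25)
  expect_error(effective_zeta(-32.5, -18, 1.2), "theta")
})

test_that("steric brush energy has the printed separation dependence", {
  prm <- citrate_params()
  T_K <- 310.15
  L <- 0.5
  expect_equal(steric_repulsion_energy(2 * L, prm, T_K), 0)
  expect_equal(steric_repulsion_energy(3 * L, prm, T_K), 0)
  # bracket at d = L: 2^2.25 - 2^-0.75 = 4.1622
  kT <- 1.380649e-23 * T_K
  pref <- 2.35 * 2 * 0.5 / (1 / sqrt(2))
  expect_equal(steric_repulsion_energy(L, prm, T_K),
               pref * 4.16219 * kT, tolerance = 1e-5)
  prm2 <- citrate_params(eta_s = 4.7)
  expect_equal(steric_repulsion_energy(L, prm2, T_K),
               2 * steric_repulsion_energy(L, prm, T_K))
  expect_error(
    steric_repulsion_energy(1, interaction_params(coating_chain_nm = NA),
                            T_K),
    "chain length"
  )
})

test_that("Debye screening length matches the electrolyte formula", {
  expect_equal(alveosim::debye_length(245) * 1e9, 0.304 / sqrt(0.245),
               tolerance = 1e-6)
})

test_that("the barrierless pair coagulates at the diffusion limit", {
  bare <- interaction_params(eta_s = 1e-9, coating_chain_nm = NA,
                             coating_density_nm2 = NA)
  med <- lining_medium(ionic_strength_mM = 100, temperature_K = 300)
  w <- stability_ratio(particle_row(d_nm = 50, zeta0 = 0),
                       particle_row(d_nm = 50, zeta0 = 0), med, bare)
  expect_equal(w, 1)
})

test_that("stability ratio is non-decreasing in zeta magnitude", {
  bare <- interaction_params(eta_s = 1e-9, coating_chain_nm = NA,
                             coating_density_nm2 = NA)
  med <- lining_medium(ionic_strength_mM = 1, temperature_K = 310.15)
  ws <- vapply(c(0, 10, 20, 30, 40, 50), function(z) {
    stability_ratio(particle_row(d_nm = 50, zeta0 = -z),
                    particle_row(d_nm = 50, zeta0 = -z), med, bare)
  }, numeric(1))
  expect_true(all(diff(ws) >= 0))
  expect_gt(ws[6], ws[1])
})

test_that("Brownian kernel has the equal-size limit and symmetry", {
  kT <- 1.380649e-23 * 310.15
  mu <- 8.79e-4
  expect_equal(brownian_kernel(20, 20, 1, mu, 310.15), 8 * kT / (3 * mu),
               tolerance = 1e-12)
  expect_equal(brownian_kernel(20, 20, 1, mu, 310.15), 1.299e-17,
               tolerance = 1e-3)
  set.seed(2)
  for (i in 1:20) {
    d1 <- runif(1, 5, 600); d2 <- runif(1, 5, 600); w <- runif(1, 1, 50)
    expect_equal(brownian_kernel(d1, d2, w, mu, 310.15),
                 brownian_kernel(d2, d1, w, mu, 310.15))
  }
  expect_equal(brownian_kernel(30, 70, 10, mu, 310.15),
               brownian_kernel(30, 70, 1, mu, 310.15) / 10)
  expect_error(brownian_kernel(20, 20, 0.5, mu, 310.15), "W")
})

test_that("a merge conserves solid volume and adsorbed inventories", {
  set.seed(6)
  bare <- interaction_params(eta_s = 1e-9, coating_chain_nm = NA,
                             coating_density_nm2 = NA)
  med <- lining_medium(ionic_strength_mM = 100)
  pop <- dplyr::bind_rows(
    particle_row(d_nm = 20, theta = 0.2, zeta0 = 0),
    particle_row(d_nm = 20, theta = 0.8, zeta0 = 0),
    particle_row(d_nm = 20, theta = 0.5, zeta0 = 0)
  )
  pop$id <- 1:3
  pop$`SP-B` <- c(3, 5, 1)
  vol0 <- sum(pop$d_nm^3)
  pl0 <- sum(pop$pl_mass_ng * pop$weight)
  beta_max <- brownian_kernel(20, 20, 1, med$viscosity, med$temperature_K)
  merged <- FALSE
  for (i in 1:20) {
    res <- dsmc_agglomeration_attempt(pop, med, bare, beta_max * 1.0001)
    if (res$merged) { merged <- TRUE; pop <- res$population; break }
  }
  expect_true(merged)
  expect_equal(nrow(pop), 3)                 # constant tracked number
  # two 20-nm monomers merge into a 20 * 2^(1/3) sphere
  expect_equal(max(pop$d_nm), 20 * 2^(1 / 3), tolerance = 1e-9)
  # solid volume (weight-corrected) conserved: one pair merged, one
  # survivor split in half
  expect_equal(sum(pop$weight * pop$d_nm^3), vol0, tolerance = 1e-12)
  expect_equal(sum(pop$weight * pop$pl_mass_ng), pl0, tolerance = 1e-12)
  expect_equal(sum(pop$weight * pop$`SP-B`), 9)
  big <- pop[which.max(pop$d_nm), ]
  expect_equal(big$n_primary, 2)
})

test_that("merged coverage is the area-weighted parent mean", {
  a <- particle_row(d_nm = 20, theta = 0.2)
  b <- particle_row(d_nm = 40, theta = 0.8)
  m <- alveosim:::merge_rows(a, b)
  aa <- pi * 20^2; ab <- pi * 40^2
  expect_equal(m$theta, (0.2 * aa + 0.8 * ab) / (aa + ab))
  expect_equal(m$d_nm, (20^3 + 40^3)^(1 / 3))
})
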