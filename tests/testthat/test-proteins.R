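# Protein corona kinetics: coverage-dependent rates, regime selection,
# attempt probabilities and footprint-capped adsorption.

custom_species <- function(ka0 = 1, kd0 = 1, beta_a = 2, n_a = 1,
                           beta_d = 0.5, n_d = 1, conc = 20,
                           mol_wt = 9, headgroup = 3, D = 5.5e-10) {
  tibble::tibble(
    species = "SP-B", class = "surface_active", mol_wt_kDa = mol_wt,
    length_nm = 7.9, headgroup_diameter_nm = headgroup,
    density_gcm3 = 1.48, conc_ug_mL = conc, diffusivity_m2s = D,
    ka0 = ka0, kd0 = kd0, beta_a = beta_a, n_a = n_a,
    beta_d = beta_d, n_d = n_d
  )
}

test_that("coverage-dependent rates follow the fitted power law", {
  sp <- custom_species(ka0 = 2, kd0 = 0.5, beta_a = 1, n_a = 1,
                       beta_d = 0.25, n_d = 2)
  r0 <- coverage_dependent_rates(sp, 0)
  expect_equal(r0$ka, 2)
  expect_equal(r0$kd, 0.5)
  r5 <- coverage_dependent_rates(custom_species(beta_a = 1, n_a = 1), 0.5)
  expect_equal(r5$ka, 1.5)         # ka0 (1 + 1 * 0.5)
  # identical enhancement cancels in the net rate
  sp_eq <- custom_species(ka0 = 3, kd0 = 2, beta_a = 0.7, n_a = 1.3,
                          beta_d = 0.7, n_d = 1.3)
  for (th in c(0, 0.3, 0.8, 1)) {
    expect_equal(coverage_dependent_rates(sp_eq, th)$ka_net, 1.5)
  }
  expect_error(coverage_dependent_rates(custom_species(kd0 = 0), 0.5),
               "kd0")
})

test_that("the slower process sets the regime", {
  sp_slow_ads <- custom_species(ka0 = 1e-12)   # tiny intrinsic rate
  expect_equal(select_regime(sp_slow_ads, 0, 1), "adsorption_limited")
  sp_fast_ads <- custom_species(ka0 = 1e3)
  # at late times the diffusive flux has decayed below any fast intrinsic
  # rate
  expect_equal(select_regime(sp_fast_ads, 0, 1e4), "diffusion_limited")
  # t = 0: the diffusive flux diverges, adsorption-limited by definition
  expect_equal(select_regime(sp_fast_ads, 0, 0), "adsorption_limited")
})

test_that("attempt probabilities scale with concentration and time", {
  sp <- custom_species(conc = 20)
  sp2 <- custom_species(conc = 40)
  p1 <- protein_attempt_probability(sp, 0, 1, "adsorption_limited")
  p2 <- protein_attempt_probability(sp2, 0, 1, "adsorption_limited")
  expect_equal(p2$p_ad, 2 * p1$p_ad)
  expect_equal(p1$dt, 1 / p1$p_ad)
  d1 <- protein_attempt_probability(sp, 0, 1, "diffusion_limited")
  d4 <- protein_attempt_probability(sp, 0, 4, "diffusion_limited")
  expect_equal(d4$p_ad, d1$p_ad / 2)     # sqrt(t) decay
  p0 <- protein_attempt_probability(custom_species(conc = 0), 0, 1,
                                    "adsorption_limited")
  expect_equal(p0$p_ad, 0)
})

test_that("acceptance frequency matches the capped attempt probability", {
  set.seed(8)
  sp <- custom_species(ka0 = 1e-12, beta_a = 0)
  pp <- protein_attempt_probability(sp, 0, 1, "adsorption_limited")
  dt <- 0.2 / pp$p_ad          # acceptance q = PAd * dt = 0.2
  n <- 1e4
  acc <- 0L
  enm <- particle_row(d_nm = 200)
  for (i in seq_len(n)) {
    res <- attempt_protein_adsorption(enm, sp, t = 1, dt = dt)
    acc <- acc + res$accepted
  }
  expect_lt(abs(acc / n - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("the footprint cap stops adsorption at surface saturation", {
  set.seed(4)
  sp <- surfactant_proteins()[2, ]       # SP-B, 3-nm headgroup
  sp$ka0 <- 1e6                          # attempts always accept
  enm <- particle_row(d_nm = 20)         # area 1257 nm^2
  cap <- floor(pi * 20^2 / (pi * 1.5^2)) # 177 molecules fit
  for (i in 1:500) {
    enm <- attempt_protein_adsorption(enm, sp, t = 1e-6)$enm
  }
  expect_equal(enm$`SP-B`, cap)
  # a headgroup larger than the particle never fits: SP-D on a 20-nm
  # particle
  spd <- surfactant_proteins()[4, ]
  spd$ka0 <- 1e6
  small <- particle_row(d_nm = 20)
  for (i in 1:20) {
    small <- attempt_protein_adsorption(small, spd, t = 1e-6)$enm
  }
  expect_equal(small$`SP-D`, 0)
})

test_that("equal mass concentrations give more molecules of lighter species", {
  prot <- surfactant_proteins()
  co_b <- alveosim:::protein_number_conc(10, 9)
  co_d <- alveosim:::protein_number_conc(10, 42)
  expect_gt(co_b, co_d)
  expect_equal(co_b / co_d, 42 / 9)
  # table baselines: surface-active species carry the fast kinetics
  expect_true(all(prot$ka0[prot$class == "surface_active"] >
                    prot$ka0[prot$class == "collectin"]))
})

test_that("zero power-law coefficients make rates coverage-independent", {
  sp <- custom_species(beta_a = 0, beta_d = 0)
  p_lo <- protein_attempt_probability(sp, 0, 1, "adsorption_limited")$p_ad
  p_hi <- protein_attempt_probability(sp, 0.9, 1, "adsorption_limited")$p_ad
  expect_equal(p_lo, p_hi)
})
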