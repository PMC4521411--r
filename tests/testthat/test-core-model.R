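# Configuration, dose conversion and control-volume construction.

test_that("inhaled number dose follows the mass-to-number conversion", {
  # 0.14 mg/m^3 x 0.5 L breath of 20-nm silver (rho 10.49):
  # 7e-5 mg inhaled / 4.3938e-14 mg per particle = 1.5931e9 particles,
  # times deposition 0.3 over 70 m^2 alveolar area
  dose <- inhaled_number_dose(0.14, 5e-4, 20, 10.49, 0.3, 70)
  expect_equal(dose, 1.59315e9 * 0.3 / 70, tolerance = 1e-4)
  expect_equal(inhaled_number_dose(0.14, 5e-4, 20, 10.49, 0, 70), 0)
  expect_error(inhaled_number_dose(0.14, 5e-4, 0, 10.49, 0.3, 70),
               "diameter")
})

test_that("control volume scales inversely with areal dose", {
  cv <- control_volume_for_N(100, 6.8278e6, 0.2e-6)
  expect_equal(cv$area_m2, 100 / 6.8278e6, tolerance = 1e-9)
  expect_equal(cv$volume_m3, cv$area_m2 * 0.2e-6)
  expect_equal(cv$number_conc_m3, 100 / cv$volume_m3)
  cv2 <- control_volume_for_N(100, 2 * 6.8278e6, 0.2e-6)
  expect_equal(cv2$area_m2, cv$area_m2 / 2)
})

test_that("scenario defaults carry the published study parameters", {
  cfg <- sim_config("invivo_human", "C20")
  expect_equal(cfg$alpha, 0.004)
  expect_equal(cfg$eta_s, 2.35)
  expect_equal(cfg$ionic_strength_mM, 245)
  expect_equal(cfg$pH, 7.28)
  expect_equal(cfg$layer_thickness_m, 0.2e-6)
  expect_equal(cfg$n_replicates, 10)
  expect_equal(sim_config("invivo_human", "P20")$eta_s, 10.6)
  nord <- sim_config("nordlund2009")
  expect_equal(nord$eta_s, 1)
  expect_false(nord$gravity)          # stirred incubation
  expect_equal(nord$pH, 7.4)
  leo <- sim_config("leo2013")
  expect_equal(leo$system_volume_mL, 4)
  expect_equal(leo$enm_conc_mg_L, 25)
  expect_equal(leo$temperature_K, 310.15)
})

test_that("config validation rejects bad values and unknown labels", {
  expect_error(sim_config("invivo_human", "C20", stop_fraction = 1.5),
               "stop_fraction")
  expect_error(sim_config("invivo_human", "C20", alpha = -1), "alpha")
  expect_error(sim_config("mars"), "valid scenarios")
  expect_error(sim_config("invivo_human", "X99"), "valid specs")
  expect_error(sim_config("invivo_human", "C20", nonsense = 1), "unknown")
})

test_that("YAML configs load with scenario defaults filled in", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("scenario: invivo_human", "enm_spec: C20", "seed: 42"), path)
  cfg <- load_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$seed, 42)
  expect_equal(cfg$alpha, 0.004)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("scenario: invivo_human", "stop_fraction: 1.5"), bad)
  expect_error(load_config(bad), "stop_fraction")
  expect_error(load_config("no/such/file.yaml"), "not found")
  for (f in c("invivo_human", "leo2013", "nordlund2009")) {
    bundled <- system.file("extdata", paste0(f, ".yaml"),
                           package = "alveosim")
    expect_s3_class(load_config(bundled), "sim_config")
  }
})

test_that("scenario construction places clean monomers at the interface", {
  scen <- build_scenario(sim_config("invivo_human", "C20"))
  pop <- scen$population
  expect_equal(nrow(pop), 100)
  expect_true(all(pop$d_nm == 20))
  expect_true(all(pop$theta == 0))
  expect_true(all(pop$depth_m == 0))
  expect_true(all(pop$n_primary == 1))
  expect_equal(scen$medium$temperature_K, 310.15)
  # same config => bit-identical construction
  scen2 <- build_scenario(sim_config("invivo_human", "C20"))
  expect_identical(scen$population, scen2$population)
  expect_identical(scen$cv, scen2$cv)
})

test_that("particle mass and diameter round-trip to 1e-9", {
  for (d in c(1.3, 20, 110, 600)) {
    m <- alveosim:::sphere_mass_ng(d, 10.49)
    expect_equal(alveosim:::sphere_diameter_nm(m, 10.49), d,
                 tolerance = 1e-9)
  }
})
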