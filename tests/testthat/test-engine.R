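# The constant-number orchestrator: stepping policy, stop rule,
# control-volume bookkeeping, conservation laws and determinism.

test_that("the time step follows the slowest-process policy", {
  expect_equal(advance_time(c(a = 1, b = 10), "slowest"), 10)
  expect_equal(advance_time(c(a = 1, b = 10), "fastest"), 1)
  expect_equal(advance_time(c(only = 3.5), "slowest"), 3.5)
  expect_equal(advance_time(c(only = 3.5), "fastest"), 3.5)
  expect_equal(advance_time(c(a = Inf, b = 2), "slowest"), 2)
  expect_error(advance_time(c(a = Inf, b = Inf)), "infinite")
})

test_that("the stop rule fires on the 1% concentration threshold", {
  cfg <- sim_config("invivo_human", "C20")
  s <- check_stop(list(t = 1, conc_ratio = 0.009), cfg)
  expect_true(s)
  expect_equal(attr(s, "reason"), "stop_fraction")
  expect_false(check_stop(list(t = 1, conc_ratio = 0.5), cfg))
  s2 <- check_stop(list(t = cfg$max_time, conc_ratio = 0.5), cfg)
  expect_true(s2)
  expect_equal(attr(s2, "reason"), "max_time")
})

test_that("control-volume resizing implements constant-number bookkeeping", {
  cv <- control_volume_for_N(100, 6.83e6, 0.2e-6)
  cv$initial_number_conc <- cv$number_conc_m3
  cv$n_tracked0 <- 100
  # no removals: unchanged
  same <- resize_control_volume(list(weight = rep(1, 100)), cv)
  expect_equal(same$volume_m3, cv$volume_m3)
  # half the represented weight removed: concentration halves while the
  # tracked count is restored, so the volume doubles
  half <- resize_control_volume(list(weight = rep(0.5, 100)), cv)
  expect_equal(half$number_conc_m3, cv$number_conc_m3 / 2)
  expect_equal(half$volume_m3, 2 * cv$volume_m3)
  expect_error(resize_control_volume(list(weight = numeric(0)), cv),
               "extinct")
})

test_that("same seed gives bit-identical runs", {
  cfg <- quick_invivo(seed = 31)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$deposited, r2$deposited)
  r3 <- run_simulation(quick_invivo(seed = 32))
  expect_false(identical(r1$trajectory, r3$trajectory))
})

test_that("core mass is conserved across a full in vivo run", {
  run <- run_simulation(quick_invivo(seed = 17))
  tr <- run$trajectory
  total <- tr$suspended_core_ng + tr$deposited_core_ng + tr$dissolved_ng
  expect_true(all(abs(total / run$initial_core_mass_ng - 1) < 1e-9))
  # times strictly increasing, one record per sweep
  expect_true(all(diff(tr$time) > 0))
  # tracked count stays at N on every record
  expect_true(all(tr$n_tracked == run$config$n_particles |
                    tr$time == max(tr$time)))
  # concentration telescopes downward to the stop threshold
  expect_true(all(diff(tr$conc_ratio) <= 1e-12))
  expect_lte(tr$conc_ratio[nrow(tr)], run$config$stop_fraction)
  expect_equal(run$stop_reason, "stop_fraction")
})

test_that("in vitro lipid mass balances the finite pool exactly", {
  cfg <- sim_config("leo2013", seed = 3, n_particles = 20, max_time = 10)
  run <- run_simulation(cfg)
  pool_used <- run$trajectory$lipid_pool_ng[1] -
    run$medium$lipid_pool_ng
  adsorbed <- sum(run$population$weight * run$population$pl_mass_ng) +
    sum(run$deposited$weight * run$deposited$pl_mass_ng)
  expect_equal(pool_used, adsorbed, tolerance = 1e-9)
  expect_gt(adsorbed, 0)
})

test_that("truncated runs are flagged", {
  cfg <- quick_invivo(seed = 19, max_time = 1e-4)
  run <- run_simulation(cfg)
  expect_equal(run$stop_reason, "max_time")
  expect_true(run$truncated)
})

test_that("transport-only transit matches the drift-diffusion mean", {
  # all transformations off: no lipid, no dissolution; proteins do not
  # alter motion. Mean first-passage time for drift v and diffusion D
  # from a reflecting top to an absorbing wall at L, starting at 0:
  # T = L/v + (D/v^2) (exp(-vL/D) - 1)
  cfg <- sim_config("invivo_human", "C20", seed = 23, n_particles = 150,
                    lipid_conc_ug_mL = 1e-12, k_diss0 = 0,
                    transport_resolution = 400, stop_fraction = 0.001)
  run <- run_simulation(cfg)
  v <- cfg$v_immersion
  L <- cfg$layer_thickness_m
  D <- 1.380649e-23 * 310.15 / (3 * pi * 8.79e-4 * 20e-9)
  T_exp <- L / v + D / v^2 * (exp(-v * L / D) - 1)
  dep <- run$deposited
  T_obs <- sum(dep$weight * dep$t_deposit) / sum(dep$weight)
  expect_equal(T_obs, T_exp, tolerance = 0.2)
})

test_that("run accessors expose tidy summaries", {
  run <- run_simulation(quick_invivo(seed = 41))
  td <- generics::tidy(run)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("time", "mean_d_nm", "mean_theta") %in% names(td)))
  gl <- generics::glance(run)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$scenario, "invivo_human")
  p <- ggplot2::autoplot(run, "coverage")
  expect_s3_class(p, "ggplot")
})
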