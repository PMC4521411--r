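# Lipid vesicle size mixture, adsorption probability, acceptance rule
# and rupture-coverage bookkeeping.

test_that("vesicle size classes hit the published percentile limits", {
  set.seed(1)
  pop <- vesicle_population()
  # class weights renormalised over light (43%) + heavy (48%) fractions
  expect_equal(pop$classes$prob, c(43, 48) / 91)
  # each class normal is parameterised so its 5th/95th percentiles sit
  # at the printed size-range limits
  z95 <- qnorm(0.95)
  expect_equal(pop$classes$mean_nm, c(35, 275))
  expect_equal(pop$classes$sd_nm, c(15, 225) / z95, tolerance = 1e-12)
  suv <- sample_vesicle_diameter(pop, 1e5, class = "SUV")
  expect_equal(mean(suv), 35, tolerance = 0.2 / 35)
  expect_equal(unname(stats::quantile(suv, 0.05)), 20, tolerance = 0.01)
  expect_equal(unname(stats::quantile(suv, 0.95)), 50, tolerance = 0.01)
  luv <- sample_vesicle_diameter(pop, 1e5, class = "LUV")
  # the LUV class is truncated at zero by resampling; compare against
  # the truncated-normal quantiles computed independently
  p0 <- pnorm(0, 275, 225 / z95)
  q_trunc <- function(p) qnorm(p0 + p * (1 - p0), 275, 225 / z95)
  expect_equal(unname(stats::quantile(luv, 0.05)), q_trunc(0.05),
               tolerance = 0.04)
  expect_equal(unname(stats::quantile(luv, 0.95)), q_trunc(0.95),
               tolerance = 0.01)
  expect_equal(unname(stats::quantile(luv, 0.95)), 500, tolerance = 0.02)
  expect_true(all(sample_vesicle_diameter(pop, 1e4) > 0))
})

test_that("adsorption probability follows the exponential size-ratio law", {
  expect_equal(vesicle_adsorption_probability(100, 20, 0, 0.004), 0)
  expect_equal(vesicle_adsorption_probability(50, 50, 1, 0.004),
               exp(-0.004))
  expect_equal(vesicle_adsorption_probability(200, 20, 0.5, 0.004),
               exp(-1.6), tolerance = 1e-12)
  p <- vesicle_adsorption_probability(runif(50, 10, 500),
                                      runif(50, 10, 600),
                                      runif(50), 0.004)
  expect_true(all(p >= 0 & p <= 1))
  expect_error(vesicle_adsorption_probability(50, 50, 1, -0.1), "alpha")
})

test_that("acceptance frequency matches Pad/(Pad+Pdiff) binomially", {
  set.seed(42)
  # near-degenerate vesicle size so Pad is fixed
  pop <- vesicle_population(mean_nm = 20, sd_nm = 1e-9)
  alpha <- -log(0.6)          # Pad = 0.6 for dves = dENM, fSA = 1
  p_diff <- 0.3               # acceptance = 0.6 / 0.9 = 2/3
  medium <- lining_medium()
  n <- 4000
  acc <- 0L
  enm <- particle_row(d_nm = 20)
  for (i in seq_len(n)) {
    res <- attempt_vesicle_adsorption(enm, pop, medium, alpha, p_diff)
    acc <- acc + res$accepted
  }
  p_exp <- 0.6 / 0.9
  expect_lt(abs(acc / n - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))
})

test_that("zero exposed area makes adsorption impossible", {
  set.seed(3)
  pop <- vesicle_population()
  enm <- particle_row(theta = 1)
  for (i in 1:50) {
    expect_false(attempt_vesicle_adsorption(enm, pop, lining_medium(),
                                            0.004, 0.001)$accepted)
  }
})

test_that("rupture adds the vesicle's patch area, capped at full cover", {
  pop <- vesicle_population()
  enm <- particle_row(d_nm = 110, theta = 0)
  enm$pl_mass_ng <- 0
  up <- apply_rupture_coverage(enm, 35, pop)
  expect_equal(up$theta, 35^2 / 110^2, tolerance = 1e-12)
  expect_equal(up$pl_mass_ng,
               up$theta * pi * 110^2 * 4 * 1.108e-12, tolerance = 1e-9)
  # a vesicle at least as large as the particle covers it completely
  big <- apply_rupture_coverage(particle_row(d_nm = 20, theta = 0), 20, pop)
  expect_equal(big$theta, 1)
  # full monolayer mass per unit area: 4 nm x 1.108 g/cm^3
  expect_equal(big$pl_mass_ng / (pi * 20^2), 4.432e-12, tolerance = 1e-6)
})

test_that("coverage is non-decreasing and lipid mass balances the pool", {
  set.seed(9)
  pop <- vesicle_population(mean_nm = 30, sd_nm = 5)
  medium <- lining_medium(lipid_pool_dynamic = TRUE, lipid_pool_ng = 1e-7,
                          lipid_pool_initial_ng = 1e-7)
  enm <- particle_row(d_nm = 120, weight = 2)
  th <- 0
  pool0 <- medium$lipid_pool_ng
  for (i in 1:200) {
    res <- attempt_vesicle_adsorption(enm, pop, medium, 0.004, 0.001)
    expect_gte(res$enm$theta, th)
    th <- res$enm$theta
    enm <- res$enm
    medium <- res$medium
  }
  # pool debit equals the weighted adsorbed mass gain, exactly
  expect_equal(pool0 - medium$lipid_pool_ng, enm$pl_mass_ng * enm$weight,
               tolerance = 1e-12)
})

test_that("MC coverage follows the mean-field expected-increment recursion", {
  set.seed(21)
  # small fixed vesicle relative to the particle: near-deterministic
  # increments, so the mean MC trajectory should track the recursion
  # theta_{k+1} = theta_k + P(theta_k)/(P+Pdiff) * (d0/dENM)^2
  d0 <- 10; dENM <- 100; alpha <- 0.004; p_diff <- 0.001
  pop <- vesicle_population(mean_nm = d0, sd_nm = 1e-9)
  n_part <- 60; n_att <- 250
  thetas <- replicate(n_part, {
    enm <- particle_row(d_nm = dENM)
    medium <- lining_medium()
    for (i in seq_len(n_att)) {
      enm <- attempt_vesicle_adsorption(enm, pop, medium, alpha, p_diff)$enm
    }
    enm$theta
  })
  th <- 0
  for (i in seq_len(n_att)) {
    pad <- vesicle_adsorption_probability(d0, dENM, 1 - th, alpha)
    th <- min(th + pad / (pad + p_diff) * (d0 / dENM)^2, 1)
  }
  se <- sd(thetas) / sqrt(n_part)
  expect_lt(abs(mean(thetas) - th), max(3 * se, 0.01))
})
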