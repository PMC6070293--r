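test_that("quasi-static GEF density follows the closed form and conserves
          the pool exactly", {
  m <- ref_mesh()
  p <- ras1_params()
  z <- gef_density(numeric(m$n), p, m)
  expect_equal(z$cgef, numeric(m$n))
  expect_equal(z$ec, p$Ectot)
  u <- gef_density(rep(10, m$n), p, m)
  expect_equal(u$ec, 7.8e-4, tolerance = 0.02)
  expect_equal(mean(u$cgef), 1.33, tolerance = 0.02)
  set.seed(3)
  for (k in 1:5) {
    crt <- runif(m$n, 0, 10^k / 100)
    g <- gef_density(crt, p, m)
    expect_lt(abs(g$ec + sum(g$cgef * m$area) - p$Ectot) / p$Ectot, 1e-9)
  }
})

test_that("stochastic activation is calibrated to a few molecules per
          second per cell and is seed-reproducible", {
  m <- ref_mesh()
  expect_equal(noise_activation(rep(38, m$n), 0, 0.01, m$area),
               numeric(m$n))
  # whole-cell activation budget rnoise * C_RD * S
  budget <- 0.002 * 38 * m$total_area
  expect_gt(budget, 5)
  expect_lt(budget, 7)
  set.seed(10)
  a <- noise_activation(rep(38, m$n), 0.002, 0.01, m$area)
  set.seed(10)
  b <- noise_activation(rep(38, m$n), 0.002, 0.01, m$area)
  expect_identical(a, b)
  # empirical mean matches dt*da*E[p]*rnoise*C_RD
  set.seed(11)
  draws <- replicate(200, sum(noise_activation(rep(38, m$n), 0.002, 0.01,
                                               m$area)))
  expect_equal(mean(draws) / 0.01, budget / 2, tolerance = 0.05)
})

test_that("with no activation pathway C_RD relaxes to jRDp / rRD", {
  m <- small_mesh()
  p <- ras1_params(k0p = 0, rnoise = 0)
  state <- list(crt = numeric(m$n), crd = rep(30, m$n),
                cgap = numeric(m$n))
  s1 <- patch_model_step(state, p, m)
  expect_equal(s1$crt, numeric(m$n))
  expect_equal(s1$crd, rep(30 + 0.01 * (0.038 - 0.001 * 30), m$n))
  for (i in 1:500) state <- patch_model_step(state, p, m)
  expect_true(all(abs(state$crd - 38) < abs(30 - 38)))
  expect_true(all(diff(range(state$crd)) < 1e-9))
})

test_that("activation, hydrolysis and noise only interconvert the two
          Ras1 pools", {
  m <- small_mesh()
  p <- ras1_params(D_RT = 0, D_RD = 0, D_GAP = 0, r_RT = 0, r_RD = 0,
                   r_GAP = 0, jRDp = 0, rnoise = 0.002)
  set.seed(4)
  state <- list(crt = runif(m$n, 0, 20), crd = runif(m$n, 10, 40),
                cgap = runif(m$n, 0, 50))
  total0 <- sum((state$crt + state$crd) * m$area)
  for (i in 1:50) state <- patch_model_step(state, p, m)
  expect_equal(sum((state$crt + state$crd) * m$area), total0,
               tolerance = 1e-12)
})

test_that("Gap1 recruitment is at half maximum at the saturation density,
          independent of the Hill exponent", {
  m <- small_mesh()
  for (h in c(2, 4)) {
    p <- ras1_params(D_GAP = 0, r_GAP = 0, h = h, rnoise = 0)
    state <- list(crt = rep(p$Csat, m$n), crd = rep(38, m$n),
                  cgap = numeric(m$n))
    s1 <- patch_model_step(state, p, m)
    expect_equal(s1$cgap, rep(p$dt * p$k3n / 2, m$n), tolerance = 1e-12)
  }
})

test_that("simulations are reproducible and clip a negligible mass", {
  m <- coarse_mesh()
  a <- run_simulation(ras1_params(), m, 100, seed = 21)
  b <- run_simulation(ras1_params(), m, 100, seed = 21)
  expect_identical(a$max_crt, b$max_crt)
  expect_identical(a$final, b$final)
  total_mass <- sum((a$final$crt + a$final$crd) * m$area)
  expect_lt(a$clip_total, 0.001 * total_mass)
})

test_that("unstable explicit steps are refused with the offending field", {
  m <- ref_mesh()
  expect_error(run_simulation(ras1_params(D_GAP = 5), m, 10, seed = 1),
               "C_GAP")
  expect_error(
    run_expanded_simulation(ras1_params(), expanded_gef_params(r_GEF = 10,
                                                               dt = 0.1),
                            m, 10, seed = 1),
    "unstable|GEF")
})

test_that("explicit GEF kinetics approach the quasi-static distribution
          when dissociation is fast", {
  m <- tiny_mesh()
  p <- ras1_params(rnoise = 0)
  tr <- run_expanded_simulation(p, expanded_gef_params(r_GEF = 1000,
                                                       dt = 5e-7),
                                m, 0.3, seed = 6, sample_stride = 0.1)
  g <- gef_density(tr$final$crt, p, m)
  expect_lt(max(abs(tr$final$cgef - g$cgef)) / max(g$cgef), 0.01)
  # explicit pool accounting stays exact
  expect_equal(tail(tr$ec, 1) + sum(tr$final$cgef * m$area), p$Ectot,
               tolerance = 1e-9)
})

test_that("recruitment constants derived from the quasi-static map equal
          explicit values", {
  m <- tiny_mesh()
  p <- ras1_params()
  derived <- run_expanded_simulation(p, expanded_gef_params(r_GEF = 50,
                                                            dt = 2e-6),
                                     m, 0.05, seed = 8)
  explicit <- run_expanded_simulation(
    p, expanded_gef_params(r_GEF = 50, rho1 = p$k1p * 50,
                           rho2 = p$k2p * 50, dt = 2e-6),
    m, 0.05, seed = 8)
  expect_identical(derived$final, explicit$final)
})

test_that("modulation profiles place the multipliers where asked", {
  m <- small_mesh()
  none <- apply_modulation_profile(rate_modulation("none"), m)
  expect_equal(none$mod0, rep(1, m$n))
  reg <- region_geodesic_disc(10, 1)
  mod <- rate_modulation("fixed_region", factor = 1.2, region = reg,
                         k2n_factor = 3, k2n_region_scale = 1.5)
  prof <- apply_modulation_profile(mod, m)
  inside <- region_mask(m, reg)
  expect_true(all(prof$mod0[inside] == 1.2))
  expect_true(all(prof$mod0[-inside] == 1))
  wider <- region_mask(m, region_geodesic_disc(10, sqrt(1.5)))
  expect_true(all(prof$mod2[wider] == 3))
  expect_gt(length(wider), length(inside))
  # patch_following without a live patch leaves rates untouched
  fol <- apply_modulation_profile(rate_modulation("patch_following",
                                                  factor = 2), m)
  expect_equal(fol$mod0, rep(1, m$n))
})

test_that("deleting Gap1-dependent hydrolysis activates the whole surface", {
  m <- ref_mesh()
  tr <- run_simulation(ras1_params(k2n = 0), m, 300, seed = 1)
  expect_equal(classify_dynamics(tr), "homogeneous_activation")
})

test_that("noise amplitude orders the regimes from quiescent to no
          discrete patch", {
  m <- ref_mesh()
  events <- vapply(c(2e-4, 2e-3), function(rn) {
    tr <- run_simulation(ras1_params(rnoise = rn), m, 400, seed = 2,
                         store_fields = FALSE)
    estimate_period(tr)$n_events
  }, 0L)
  expect_lte(events[1], 1)        # below threshold: no re-formation
  expect_lte(events[1], events[2])
  high <- run_simulation(ras1_params(rnoise = 0.02), m, 400, seed = 2)
  expect_false(classify_dynamics(high) %in%
                 c("single_oscillating", "stable_single_patch",
                   "single_oscillating_occasional_two"))
})
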