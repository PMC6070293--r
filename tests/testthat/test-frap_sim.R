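test_that("no transport means no recovery; exchange restores steady state", {
  m <- small_mesh()
  prot <- protocol_side_bleach(2, slab_half_width = Inf)
  frozen <- simulate_frap_uniform(m, uniform_exchange_params(D = 0, r = 0),
                                  prot, 10)
  post <- frozen$times >= 0
  expect_true(all(frozen$intensity[post, "bleached"] == 0))
  # with exchange the unique fixed point j+/r is restored everywhere
  rec <- simulate_frap_uniform(m, uniform_exchange_params(D = 0.1, r = 0.05,
                                                          j_plus = 0.05),
                               prot, 400)
  expect_equal(unname(tail(rec$intensity[, "bleached"], 1)), 1,
               tolerance = 1e-6)
})

test_that("side-strip recovery matches the 1D periodic diffusion solution", {
  m <- long_mesh()
  oracle <- function(w, D, S, tt, nmax = 400) {
    k <- seq_len(nmax)
    ak <- -2 * sin(pi * k * w / S) / (pi * k)
    mk <- sin(pi * k * w / S) / (pi * k * w / S)
    vapply(tt, function(t) {
      (1 - w / S) + sum(ak * mk * exp(-D * (2 * pi * k / S)^2 * t))
    }, 0)
  }
  t50 <- numeric(2)
  for (i in 1:2) {
    w <- c(1.5, 4.0)[i]
    prot <- protocol_side_bleach(w, slab_half_width = Inf)
    prot$bleach_region$circ_extent <- Inf
    prot$readout_regions$bleached$circ_extent <- Inf
    tr <- simulate_frap_uniform(m, uniform_exchange_params(D = 0.15),
                                prot, 40)
    post <- tr$times >= 1
    ana <- oracle(w, 0.15, m$s_total, tr$times[post])
    num <- tr$intensity[post, "bleached"]
    expect_lt(max(abs(num - ana)), 0.03)
    t50[i] <- tr$times[post][min(which(num >= 0.5))]
  }
  expect_lt(t50[1], t50[2])  # narrow strips recover faster
})

test_that("tip-recruitment FRAP recovers to the post-bleach amplitude
          fraction, middle before sides", {
  m <- ref_mesh()
  tr <- simulate_frap_recruitment(
    m, recruitment_params(0.2, 0.02, sigma = 0.4,
                          post_bleach_amp_factor = 0.5),
    protocol_fusion_focus(), 400)
  expect_equal(unname(tail(tr$intensity[, "tip"], 1)), 0.5,
               tolerance = 0.01)
  half_time <- function(reg) {
    post <- tr$times >= 0
    y <- tr$intensity[post, reg]
    tr$times[post][min(which(y >= tail(y, 1) / 2))]
  }
  expect_lt(half_time("middle"), half_time("sides"))

  tr2 <- simulate_frap_recruitment(
    m, recruitment_params(0.2, 0.02, sigma = 0.8,
                          post_bleach_amp_factor = 0.7),
    protocol_half_tip(), 400)
  expect_equal(unname(tail(tr2$intensity[, "bleached"], 1)), 0.7,
               tolerance = 0.01)
})

test_that("steady-state recruitment profile scales linearly with amplitude", {
  m <- small_mesh()
  prot <- protocol_fusion_focus(dt = 0.02)
  t1 <- simulate_frap_recruitment(m, recruitment_params(0.2, 0.02, A = 50),
                                  prot, 5)
  t2 <- simulate_frap_recruitment(m, recruitment_params(0.2, 0.02, A = 100),
                                  prot, 5)
  expect_equal(t2$prebleach, 2 * t1$prebleach, tolerance = 1e-4)
})

test_that("immobile-fraction control: without diffusion the non-bleached
          half cannot reproduce the mobile decay", {
  m <- ref_mesh()
  prot <- protocol_half_tip()
  mobile <- simulate_frap_recruitment(
    m, recruitment_params(0.2, 0.02, sigma = 0.8,
                          post_bleach_amp_factor = 0.7), prot, 120)
  frozen <- simulate_frap_recruitment(
    m, recruitment_params(0, 0.08, sigma = 0.8,
                          post_bleach_amp_factor = 0.7), prot, 120)
  dmax <- max(abs(mobile$intensity[, "nonbleached"] -
                    frozen$intensity[, "nonbleached"]))
  expect_gt(dmax, 0.05)
})

test_that("photobleach correction inverts a constructed decay", {
  tt <- 0:100
  true_curve <- 1 - 0.6 * exp(-tt / 20)
  bg <- 7
  r_pb <- 0.01
  raw <- true_curve * exp(-r_pb * tt) + bg
  cyt <- 2.5 * exp(-r_pb * tt) + bg
  fit <- correct_photobleaching(tt, raw, cyt, background = bg)
  expect_equal(fit$r_PB, r_pb, tolerance = 0.01)
  expect_equal(as.vector(fit$intensity), true_curve, tolerance = 0.01)
  # r_PB = 0 reduces to background subtraction
  id <- correct_photobleaching(tt, raw, cyt, background = bg, r_PB = 0)
  expect_equal(as.vector(id$intensity), raw - bg)
  # constant cytosol fits no decay
  flat <- correct_photobleaching(tt, raw, rep(3, length(tt)) + bg,
                                 background = bg)
  expect_equal(flat$r_PB, 0)
  expect_error(correct_photobleaching(tt, raw, rep(bg, length(tt)),
                                      background = bg), "not positive")
})

test_that("grid fit is self-consistent on noise-free synthetic input", {
  m <- interphase_mesh()
  prot <- protocol_side_bleach(4)
  tr <- synthetic_frap_traces(
    uniform_exchange_params(0.15, 0.001, j_plus = 0.001), prot, m, 60,
    noise_sd = 0, n_cells = 1, seed = 1)
  fit <- fit_frap_params(tr, "uniform", D_grid = c(0.05, 0.1, 0.15, 0.2),
                         r_grid = c(0, 0.001, 0.01), mesh = m)
  expect_equal(unname(fit$best), c(0.15, 0.001))
  # an infinitely wide band accepts the whole grid
  tr$sd[] <- Inf
  fit2 <- fit_frap_params(tr, "uniform", D_grid = c(0.05, 0.15),
                          r_grid = c(0, 0.01), mesh = m)
  expect_true(all(fit2$grid$acceptable))
  expect_false(fit2$out_of_band)
})

test_that("synthetic fixtures are deterministic with calibrated noise", {
  m <- tiny_mesh()
  prot <- protocol_side_bleach(2, slab_half_width = Inf, dt = 0.02)
  base <- simulate_frap_uniform(m, uniform_exchange_params(0.15, 0.001,
                                                           j_plus = 0.001),
                                prot, 20)
  exact <- synthetic_frap_traces(NULL, prot, m, 20, noise_sd = 0,
                                 n_cells = 3, seed = 5, base_trace = base)
  expect_true(all(exact$sd == 0))
  a <- synthetic_frap_traces(NULL, prot, m, 20, noise_sd = 0.05,
                             n_cells = 5, seed = 9, base_trace = base)
  b <- synthetic_frap_traces(NULL, prot, m, 20, noise_sd = 0.05,
                             n_cells = 5, seed = 9, base_trace = base)
  expect_identical(a$intensity, b$intensity)
  expect_identical(a$sd, b$sd)
  # sampling distribution of the per-frame SD over 200 seeds: the sample
  # SD of 5 normals has expectation c4(5) * sigma with c4(5) ~ 0.940
  sds <- vapply(1:200, function(s) {
    mean(synthetic_frap_traces(NULL, prot, m, 20, noise_sd = 0.05,
                               n_cells = 5, seed = s,
                               base_trace = base)$sd)
  }, 0)
  expect_equal(mean(sds), 0.940 * 0.05, tolerance = 0.02)
})

test_that("(D, r) recovery lands within one grid step on noisy replicates", {
  m <- interphase_mesh()
  prot_l <- protocol_side_bleach(4)
  prot_s <- protocol_side_bleach(1.5)
  base_l <- simulate_frap_uniform(m, uniform_exchange_params(0.04, 0.02,
                                                             j_plus = 0.02),
                                  prot_l, 80)
  base_s <- simulate_frap_uniform(m, uniform_exchange_params(0.04, 0.02,
                                                             j_plus = 0.02),
                                  prot_s, 80)
  cache <- new.env()
  hits <- 0
  n_rep <- 20
  for (rep in seq_len(n_rep)) {
    t_l <- synthetic_frap_traces(NULL, prot_l, m, 80, 0.05, 5,
                                 seed = 100 + rep, base_trace = base_l)
    t_s <- synthetic_frap_traces(NULL, prot_s, m, 80, 0.05, 5,
                                 seed = 300 + rep, base_trace = base_s)
    fit <- fit_frap_params(list(t_l, t_s), "uniform",
                           D_grid = seq(0.01, 0.08, 0.01),
                           r_grid = seq(0, 0.04, 0.005), mesh = m,
                           sim_cache = cache)
    if (abs(fit$best["D"] - 0.04) <= 0.01 + 1e-9 &&
        abs(fit$best["r"] - 0.02) <= 0.005 + 1e-9) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 0.9 * n_rep)
})

test_that("trace CSV round-trips through the long format", {
  m <- tiny_mesh()
  prot <- protocol_side_bleach(2, slab_half_width = Inf, dt = 0.02)
  tr <- synthetic_frap_traces(uniform_exchange_params(0.1, 0.01,
                                                      j_plus = 0.01),
                              prot, m, 10, noise_sd = 0.02, n_cells = 3,
                              seed = 2)
  path <- tempfile(fileext = ".csv")
  write_frap_csv(tr, path, comment = "test fixture")
  back <- read_frap_csv(path)
  expect_equal(back$times, tr$times)
  expect_equal(unname(back$intensity), unname(tr$intensity),
               tolerance = 1e-12)
  expect_equal(unname(back$sd), unname(tr$sd), tolerance = 1e-12)
  unlink(path)
})
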