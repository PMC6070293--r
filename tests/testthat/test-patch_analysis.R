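gauss_bump <- function(mesh, center, amp, width = 0.4) {
  d <- geodesic_distances(mesh, center)
  amp * exp(-d^2 / (2 * width^2))
}

test_that("patch detection finds constructed bumps and ignores flat
          fields", {
  m <- small_mesh()
  pol <- patch_threshold(abs_floor = 5, rel_max = 0.25)
  expect_length(detect_patches(rep(3, m$n), m, pol), 0)
  c1 <- which.min(abs(m$z - 0.5) + abs(ras1zone:::angdiff(m$phi, 0)))
  one <- gauss_bump(m, c1, 100) + 1
  p1 <- detect_patches(one, m, pol)
  expect_length(p1, 1)
  expect_equal(p1[[1]]$center, c1)
  c2 <- which.min(abs(m$z + 0.5) + abs(ras1zone:::angdiff(m$phi, pi)))
  two <- gauss_bump(m, c1, 100) + gauss_bump(m, c2, 80) + 1
  p2 <- detect_patches(two, m, pol)
  expect_length(p2, 2)
  # each detected patch is a connected component
  for (p in p2) {
    sub <- igraph::induced_subgraph(
      igraph::graph_from_edgelist(as.matrix(m$edges[, c("i", "j")]),
                                  directed = FALSE), p$cells)
    expect_true(igraph::is_connected(sub))
  }
})

test_that("axial profiles are flat for uniform fields and conserve strip
          content", {
  m <- ref_mesh()
  flat <- axial_profile(list(crt = rep(5, m$n)), m, through_cell = 900)
  expect_true(all(abs(flat$crt - 5) < 1e-12))
  set.seed(2)
  f <- runif(m$n, 0, 10)
  idx <- region_mask(m, region_axial_strip(900, 0.2))
  prof <- axial_profile(list(crt = f), m, 900)
  # quadrature consistency: per-ring means weighted by the in-strip cell
  # area reproduce the total strip content
  ring <- round(m$s[idx], 6)
  ring_area <- tapply(m$area[idx], ring, sum)
  ord <- match(prof$position, as.numeric(names(ring_area)))
  content <- sum(prof$crt * ring_area[ord])
  expect_equal(content, sum(f[idx] * m$area[idx]), tolerance = 0.02)
})

test_that("period estimation recovers a known oscillation and flags
          sparse series", {
  tt <- 0:599
  osc <- list(times = tt, max_crt = 50 + 40 * sin(2 * pi * tt / 60))
  e <- estimate_period(osc)
  expect_equal(e$period, 60, tolerance = 0.01)
  expect_false(e$stable)
  few <- list(times = 0:99, max_crt = c(rep(1, 40), 1 + dnorm(41:99, 50, 3)))
  e2 <- estimate_period(few)
  expect_true(is.na(e2$period))
  expect_lt(e2$n_events, 2)
  flatline <- list(times = tt, max_crt = rep(30, 600) + c(rnorm(300, 0, 0.01),
                                                          rep(0, 300)))
  expect_true(estimate_period(flatline)$stable)
})

test_that("classifier rules label constructed regimes", {
  m <- small_mesh()
  nf <- 60
  # everything GTP-dominated -> homogeneous activation
  hom <- fake_trajectory(m, matrix(50, m$n, nf),
                         crd = matrix(1, m$n, nf))
  expect_equal(classify_dynamics(hom), "homogeneous_activation")
  # flat low field -> no patch
  none <- fake_trajectory(m, matrix(0.5, m$n, nf),
                          crd = matrix(38, m$n, nf))
  expect_equal(classify_dynamics(none), "no_patch")
  # one fixed bump, constant in time -> stable single patch
  bump <- gauss_bump(m, 40, 80) + 0.5
  stab <- fake_trajectory(m, matrix(bump, m$n, nf),
                          crd = matrix(38, m$n, nf))
  expect_equal(classify_dynamics(stab), "stable_single_patch")
  # single-cell spikes -> minimum size patch
  spike <- matrix(0.5, m$n, nf)
  spike[7, ] <- 60
  spike[7, seq(1, nf, 10)] <- 0.5   # intermittent so it is not "stable"
  mini <- fake_trajectory(m, spike, crd = matrix(38, m$n, nf))
  expect_equal(classify_dynamics(mini), "minimum_size_patch")
})

test_that("reference parameters yield a localized Ras1-GTP patch with a
          wider Gap1 halo", {
  tr <- reference_trajectory(seed = 2)
  st <- ras1zone:::trajectory_frame_stats(tr)
  expect_gt(max(st$n_patches), 0)
  pk <- which.max(tr$max_crt)
  ctr <- tr$argmax_crt[pk]
  prof <- axial_profile(list(crt = tr$crt[, pk], cgap = tr$cgap[, pk]),
                        tr$mesh, ctr)
  w_rt <- profile_fwhm(prof, "crt")
  w_gap <- profile_fwhm(prof, "cgap")
  expect_gt(w_gap, w_rt)
})

test_that("phase scans are deterministic and label the degenerate
          activation-free row as patchless", {
  m <- coarse_mesh()
  grid <- data.frame(k0p = c(0, 0), k2n = c(0.05, 0.1))
  a <- phase_scan(grid, ras1_params(), m, duration = 120, seed = 5)
  b <- phase_scan(grid, ras1_params(), m, duration = 120, seed = 5)
  expect_identical(a$label, b$label)
  expect_true(all(a$label == "no_patch"))
  expect_true(all(is.na(a$error)))
})

test_that("profile patch counting follows the experimental rules", {
  px <- 0.13
  base <- rep(100, 60)
  # two 4-px bright runs with a 1-px gap merge into one 9-px patch
  prof <- base
  prof[20:23] <- 200
  prof[25:28] <- 200
  prof[24] <- 101   # above background mean but between bright runs
  res <- quantify_profile_patches(prof, 100, 10, pixel_size = px)
  expect_equal(nrow(res), 1)
  expect_equal(res$size_um, 9 * px, tolerance = 1e-12)
  # a single-pixel spike is below the minimum region size
  spike <- base
  spike[30] <- 500
  expect_equal(nrow(quantify_profile_patches(spike, 100, 10)), 0)
  # flat background yields nothing
  expect_equal(nrow(quantify_profile_patches(base, 100, 10)), 0)
  # dim runs above the mean but below mean + 3 SD do not qualify
  dim2 <- base
  dim2[10:14] <- 115
  expect_equal(nrow(quantify_profile_patches(dim2, 100, 10)), 0)
  expect_error(quantify_profile_patches(c(base, NA), 100, 10),
               "non-finite")
})

test_that("stronger Gap1 recruitment narrows the patch and stronger
          activation multiplies it", {
  m <- ref_mesh()
  peak_width <- function(tr) {
    pk <- ras1zone:::peak_indices(tr$max_crt,
                                  0.25 * diff(range(tr$max_crt)))
    if (length(pk) == 0) pk <- which.max(tr$max_crt)
    median(vapply(pk, function(f) {
      prof <- axial_profile(list(crt = tr$crt[, f]), tr$mesh,
                            tr$argmax_crt[f])
      profile_fwhm(prof, "crt")
    }, 0), na.rm = TRUE)
  }
  tr_ref <- reference_trajectory(seed = 2)
  tr_k3 <- run_simulation(ras1_params(k3n = 500), m, 600, seed = 2)
  expect_lt(peak_width(tr_k3), peak_width(tr_ref))
  mean_count <- function(tr) {
    st <- ras1zone:::trajectory_frame_stats(tr)
    with_patch <- st$n_patches[st$n_patches > 0 & st$time > 100]
    mean(with_patch)
  }
  tr_k0 <- run_simulation(ras1_params(k0p = 0.032), m, 600, seed = 2)
  expect_gt(mean_count(tr_k0), mean_count(tr_ref))
})

test_that("stable patch size varies little across tip curvatures at fixed
          area", {
  sizes <- vapply(c(1.8, 2.0, 2.3), function(rt) {
    r <- min(rt, 2)
    m <- cached_mesh(paste0("tipvar", rt), r, equal_area_length(r, rt),
                     45, 40, tip_radius = rt)
    tr <- run_simulation(ras1_params(Csat = 20, k2n = 0.01), m, 400,
                         seed = 3)
    p <- detect_patches(tr$crt[, ncol(tr$crt)], m)
    max(vapply(p, function(q) length(q$cells), 0L))
  }, 0L)
  expect_lte(max(sizes) - min(sizes), 4)
})
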