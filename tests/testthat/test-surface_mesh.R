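test_that("reference mesh reproduces the analytic spherocylinder geometry", {
  m <- ref_mesh()
  expect_lt(abs(m$total_area - 24 * pi) / (24 * pi), 0.01)
  expect_lt(abs(m$enclosed_volume - m$analytic_volume) / m$analytic_volume,
            0.01)
  expect_true(all(m$area > 0))
  # closed surface: every cell has neighbors, the graph is connected,
  # and no adjacency pair is duplicated
  deg <- table(c(m$edges$i, m$edges$j))
  expect_equal(length(deg), m$n)
  expect_false(any(duplicated(paste(m$edges$i, m$edges$j))))
  g <- igraph::graph_from_edgelist(as.matrix(m$edges[, c("i", "j")]),
                                   directed = FALSE)
  expect_true(igraph::is_connected(g))
})

test_that("Voronoi polygon areas stay within the working range", {
  m <- ref_mesh()
  expect_gte(min(m$area), 0.017)
  expect_lte(max(m$area), 0.046)
})

test_that("degenerate geometry is rejected", {
  expect_error(mesh_spec(2, 3, 45, 40), "invalid geometry")
  expect_error(mesh_spec(2, 6, 45, 40, tip_radius = 1.5))
})

test_that("Laplace-Beltrami annihilates constants and conserves mass", {
  m <- small_mesh()
  expect_equal(apply_laplace_beltrami(m, rep(3.7, m$n)), rep(0, m$n))
  set.seed(42)
  for (k in 1:5) {
    f <- rnorm(m$n, sd = 10^k)
    lf <- apply_laplace_beltrami(m, f)
    expect_lt(abs(sum(m$area * lf)), 1e-9 * sum(m$area * abs(f)))
  }
  expect_error(apply_laplace_beltrami(m, rnorm(m$n - 1)), "length")
  expect_error(apply_laplace_beltrami(m, c(NA, rnorm(m$n - 1))),
               "non-finite")
})

test_that("point-source diffusion matches the flat heat kernel on the
          cylindrical midsection", {
  m <- long_mesh()
  D <- 0.1
  t_end <- 2
  i0 <- which.min(abs(m$z) + abs(ras1zone:::angdiff(m$phi, pi)))
  f <- numeric(m$n)
  f[i0] <- 1 / m$area[i0]
  res <- ras1zone:::integrate_linear_cpp(
    m$edges$i, m$edges$j, m$edges$weight, m$area, f, D, 0,
    numeric(m$n), 0.002, 1000L, 1000L, list(), FALSE, 0)
  circ <- 2 * pi * m$spec$radius
  arc <- ras1zone:::angdiff(m$phi, m$phi[i0]) * m$spec$radius
  ana <- 0
  for (k in -2:2) {
    ana <- ana + exp(-((arc + k * circ)^2 + (m$z - m$z[i0])^2) /
                       (4 * D * t_end))
  }
  ana <- ana / (4 * pi * D * t_end)
  sel <- abs(m$z) < 6   # stay on the intrinsically flat section
  l2 <- sqrt(sum(m$area[sel] * (res$C[sel] - ana[sel])^2) /
               sum(m$area[sel] * ana[sel]^2))
  expect_lt(l2, 0.05)
  expect_equal(sum(m$area * res$C), 1, tolerance = 1e-10)
})

test_that("pole-source diffusion matches the axisymmetric capsule solution", {
  m <- ref_mesh()
  D <- 0.1
  t_end <- 1.5
  i0 <- which.min(m$s)
  f <- numeric(m$n)
  f[i0] <- 1 / m$area[i0]
  res <- ras1zone:::integrate_linear_cpp(
    m$edges$i, m$edges$j, m$edges$weight, m$area, f, D, 0,
    numeric(m$n), 0.002, 750L, 750L, list(), FALSE, 0)
  ref <- axisymmetric_pole_kernel(m, D, t_end)
  ana <- approx(ref$s, ref$C, xout = m$s, rule = 2)$y
  l2 <- sqrt(sum(m$area * (res$C - ana)^2) / sum(m$area * ana^2))
  expect_lt(l2, 0.05)
})

test_that("2x grid refinement changes the diffusion profile by < 2%", {
  D <- 0.05
  t_end <- 10
  prof <- lapply(list(cached_mesh("conv1", 2, 6, 32, 28),
                      cached_mesh("conv2", 2, 6, 64, 56)), function(m) {
    i0 <- which.min(m$s)   # pole source: axisymmetric, comparable by s
    f <- numeric(m$n)
    f[i0] <- 1 / m$area[i0]
    res <- ras1zone:::integrate_linear_cpp(
      m$edges$i, m$edges$j, m$edges$weight, m$area, f, D, 0,
      numeric(m$n), 0.005, 2000L, 2000L, list(), FALSE, 0)
    list(s = m$s, C = res$C, a = m$area)
  })
  grid_s <- seq(0.2, 7.5, by = 0.1)
  p1 <- approx(prof[[1]]$s, prof[[1]]$C, xout = grid_s,
               ties = mean)$y
  p2 <- approx(prof[[2]]$s, prof[[2]]$C, xout = grid_s,
               ties = mean)$y
  expect_lt(sqrt(mean((p1 - p2)^2) / mean(p2^2)), 0.02)
})

test_that("region masks select the expected geometry", {
  m <- ref_mesh()
  strip <- region_mask(m, region_side_strip(4, circ_extent = 6.28))
  expect_lt(abs(sum(m$area[strip]) - 4 * 6.28), 0.05 * 4 * 6.28)
  half <- region_mask(m, region_half_tip("front"))
  cap_area <- 2 * pi * m$spec$radius^2
  expect_lt(abs(sum(m$area[half]) - cap_area / 2), 0.05 * cap_area)
  expect_identical(region_mask(m, region_geodesic_disc(17, 0)), 17L)
  expect_warning(
    empty <- region_mask(m, region_side_strip(0.0001,
                                              axial_center = 2.9)),
    "no cells")
  expect_length(empty, 0)
})

test_that("blunter-tip meshes at fixed total area stay closed and
          conservative", {
  L <- equal_area_length(2, 2.3)
  m <- cached_mesh("blunt", 2, L, 45, 40, tip_radius = 2.3)
  expect_lt(abs(m$total_area - 24 * pi) / (24 * pi), 0.01)
  g <- igraph::graph_from_edgelist(as.matrix(m$edges[, c("i", "j")]),
                                   directed = FALSE)
  expect_true(igraph::is_connected(g))
  set.seed(7)
  f <- rnorm(m$n)
  expect_lt(abs(sum(m$area * apply_laplace_beltrami(m, f))),
            1e-9 * sum(m$area * abs(f)))
})

test_that("PLY and VTK exports round-trip areas and fields", {
  m <- small_mesh()
  set.seed(11)
  fld <- list(crt = runif(m$n, 0, 1000))
  pairs <- list(list(w = write_mesh_ply, r = read_mesh_ply),
                list(w = write_mesh_vtk, r = read_mesh_vtk))
  for (p in pairs) {
    path <- tempfile()
    p$w(m, path, fields = fld)
    back <- p$r(path)
    expect_equal(back$fields$area, m$area, tolerance = 1e-12)
    expect_equal(back$fields$crt, fld$crt, tolerance = 1e-12)
    expect_equal(unname(as.matrix(back$points)), unname(m$centroid),
                 tolerance = 1e-12)
    unlink(path)
  }
})

test_that("geodesic distances are zero at the source and metric-plausible", {
  m <- small_mesh()
  d <- geodesic_distances(m, 5)
  expect_equal(d[5], 0)
  chord <- sqrt(colSums((t(m$generator) - m$generator[5, ])^2))
  expect_true(all(d >= chord - 1e-9))
  expect_lt(max(d), m$s_total + pi * m$spec$radius)
})
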