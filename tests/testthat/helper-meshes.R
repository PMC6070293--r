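# report every failure instead of truncating the run at the default cap
options(testthat.progress.max_fails = 200)

# meshes are deterministic and moderately expensive to build: construct
# each geometry once per test run and share it across files
.mesh_cache <- new.env(parent = emptyenv())

cached_mesh <- function(key, ...) {
  if (is.null(.mesh_cache[[key]])) {
    .mesh_cache[[key]] <- build_mesh(mesh_spec(...))
  }
  .mesh_cache[[key]]
}

ref_mesh <- function() cached_mesh("ref", 2, 6, 45, 40)          # mating cell
coarse_mesh <- function() cached_mesh("coarse", 2, 6, 23, 20)    # 2x coarse
small_mesh <- function() cached_mesh("small", 2, 6, 20, 16)
tiny_mesh <- function() cached_mesh("tiny", 2, 6, 10, 8)
long_mesh <- function() cached_mesh("long", 2, 16, 120, 40)      # side FRAP
interphase_mesh <- function() cached_mesh("inter", 2, 11, 41, 20)

# axisymmetric reference solution for a pole point source on the capsule:
# 1D finite-volume solve in the meridian arc coordinate with the exact
# surface-of-revolution metric (independent of the 2D mesh operator)
axisymmetric_pole_kernel <- function(mesh, D, t_end, ns = 800) {
  S <- mesh$s_total
  h <- S / ns
  sc <- (seq_len(ns) - 0.5) * h
  r <- mesh$spec$radius
  rt <- mesh$spec$tip_radius
  hc <- mesh$hc
  zc <- hc - sqrt(max(0, rt^2 - r^2))
  rho_at <- function(s) {
    ras1zone:::surface_at(s, r, hc, rt, zc, mesh$s_cap, S)[["rho"]]
  }
  rho <- vapply(sc, rho_at, 0)
  rho_f <- vapply(seq_len(ns - 1) * h, rho_at, 0)
  a1 <- 2 * pi * rho * h
  C <- numeric(ns)
  C[1] <- 1 / a1[1]
  dt <- 0.15 * h^2 / (2 * D)
  nt <- ceiling(t_end / dt)
  dt <- t_end / nt
  for (it in seq_len(nt)) {
    flux <- 2 * pi * rho_f * D * diff(C) / h
    C <- C + dt * (c(flux, 0) - c(0, flux)) / a1
  }
  list(s = sc, C = C)
}

# shared reference trajectories (Table-1 parameter set), computed once
.traj_cache <- new.env(parent = emptyenv())

reference_trajectory <- function(seed = 2, duration = 600) {
  key <- sprintf("ref_%d_%d", seed, duration)
  if (is.null(.traj_cache[[key]])) {
    .traj_cache[[key]] <- run_simulation(ras1_params(), ref_mesh(),
                                         duration, seed = seed)
  }
  .traj_cache[[key]]
}

# minimal hand-built trajectory for classifier rule tests
fake_trajectory <- function(mesh, crt, crd = NULL, times = NULL) {
  nf <- ncol(crt)
  if (is.null(times)) times <- seq_len(nf) - 1
  structure(list(
    times = times,
    max_crt = apply(crt, 2, max),
    argmax_crt = apply(crt, 2, which.max),
    crt = crt, crd = crd, cgap = NULL,
    mesh = mesh, params = ras1_params(), model = "quasi_static"
  ), class = "ras1_trajectory")
}
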