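#' Quasi-static GEF surface density and free cytoplasmic pool
#'
#' The positive feedback distributes a finite cytoplasmic GEF pool onto the
#' membrane in proportion to the local Ras1-GTP density and its square:
#' `C_GEF = (k1p Ec / V) C_RT + (k2p Ec / V) C_RT^2`, where the free pool
#' `Ec` follows from GEF number conservation in closed form,
#' `Ec = Ectot / (1 + integral[(k1p C_RT + k2p C_RT^2)/V] da)`, so that
#' `Ec + sum(C_GEF * area)` equals `Ectot` exactly.
#'
#' @param crt per-cell Ras1-GTP surface density (um^-2), nonnegative.
#' @param params a [ras1_params()] object.
#' @param mesh a [build_mesh()] result.
#' @return list with `cgef` (per-cell GEF density, um^-2) and `ec` (free
#'   cytoplasmic GEF, molecules).
#' @export
#' @examples
#' \donttest{
#' m <- build_mesh(mesh_spec(2, 6, 45, 40))
#' gef_density(rep(10, m$n), ras1_params(), m)$ec   # ~7.8e-4 molecules
#' }
gef_density <- function(crt, params, mesh) {
  stopifnot(length(crt) == mesh$n, all(crt >= 0))
  v <- if (is.null(params$V)) mesh$enclosed_volume else params$V
  integral <- sum(mesh$area * (params$k1p * crt + params$k2p * crt^2)) / v
  ec <- params$Ectot / (1 + integral)
  cgef <- (params$k1p * ec / v) * crt + (params$k2p * ec / v) * crt^2
  list(cgef = cgef, ec = ec)
}

#' Stochastic background activation of Ras1
#'
#' Draws the number of Ras1 molecules spontaneously activated in one
#' integration step on each Voronoi cell:
#' `dN = dt * da * p * rnoise * C_RD` with `p ~ U(0,1)` drawn independently
#' per cell. The caller moves `dN/da` from the Ras1-GDP to the Ras1-GTP
#' field. With the reference background density the whole-cell mean
#' activation budget `rnoise * C_RD * S` is about 6 molecules per second.
#'
#' @param crd per-cell Ras1-GDP density (um^-2).
#' @param rnoise noise amplitude (1/s).
#' @param dt integration step (s).
#' @param areas per-cell areas (um^2).
#' @return numeric vector of activated molecule counts per cell.
#' @export
noise_activation <- function(crd, rnoise, dt, areas) {
  if (rnoise == 0) return(numeric(length(crd)))
  dt * areas * runif(length(crd)) * rnoise * crd
}

#' One forward-Euler step of the patch model
#'
#' Advances the three surface fields by one explicit step of the
#' reaction-diffusion system (GEF recomputed quasi-statically from the
#' current Ras1-GTP field; optional per-cell multipliers on `k0p`/`k2n`;
#' noise applied as a Ras1-GDP to Ras1-GTP transfer; negative densities
#' clipped at zero with the clipped mass returned).
#'
#' @param state list with numeric fields `crt`, `crd`, `cgap`.
#' @param params a [ras1_params()] object.
#' @param mesh a [build_mesh()] result.
#' @param mod0,mod2 per-cell multipliers on `k0p` / `k2n` (default all 1).
#' @return updated state list; components `ec`, `cgef` (post-step) and
#'   `clipped` (molecules removed by the nonnegativity clip) attached.
#' @export
patch_model_step <- function(state, params, mesh, mod0 = NULL, mod2 = NULL) {
  if (is.null(mod0)) mod0 <- rep(1, mesh$n)
  if (is.null(mod2)) mod2 <- rep(1, mesh$n)
  check_stability(mesh, params$dt,
                  list(C_RT = params$D_RT, C_RD = params$D_RD,
                       C_GAP = params$D_GAP))
  res <- integrate_patch_cpp(mesh$edges$i, mesh$edges$j, mesh$edges$weight,
                             mesh$area, params_vector(params, mesh),
                             state$crt, state$crd, state$cgap,
                             mod0, mod2, params$dt, 1L, 1L, FALSE)
  g <- gef_density(res$CRT, params, mesh)
  list(crt = res$CRT, crd = res$CRD, cgap = res$CGAP,
       cgef = g$cgef, ec = g$ec, clipped = res$clip_total)
}

#' Rate modulation: localized change of feedback rate constants
#'
#' Describes a spatial modulation of the activation rate constant `k0p`
#' and/or the Gap1-dependent hydrolysis constant `k2n`, emulating locally
#' sensed pheromone:
#'
#' * `mode = "none"` — no modulation.
#' * `mode = "fixed_region"` — `factor` applied inside a fixed [regions]
#'   spec.
#' * `mode = "patch_following"` — `factor` applied on a geodesic disc of
#'   radius `radius` recentered on the live patch center every
#'   `recenter_every` seconds of simulated time.
#'
#' `k2n_factor` (with optional `k2n_region_scale`, an area multiplier
#' realized as a `sqrt(scale)`-times-larger disc radius) modulates the
#' negative feedback over a concentric region.
#'
#' @param mode one of `"none"`, `"fixed_region"`, `"patch_following"`.
#' @param factor multiplier on `k0p` inside the region.
#' @param region a [regions] spec (fixed_region mode).
#' @param radius geodesic disc radius (um, patch_following mode).
#' @param recenter_every recentering interval (s, patch_following mode).
#' @param k2n_factor multiplier on `k2n` inside the (scaled) region.
#' @param k2n_region_scale area scale of the `k2n` region relative to the
#'   `k0p` region.
#' @return a `rate_modulation` object.
#' @export
rate_modulation <- function(mode = c("none", "fixed_region",
                                     "patch_following"),
                            factor = 1, region = NULL, radius = 1,
                            recenter_every = 1, k2n_factor = 1,
                            k2n_region_scale = 1) {
  mode <- match.arg(mode)
  stopifnot(factor > 0, k2n_factor > 0, radius > 0, k2n_region_scale > 0)
  if (mode == "fixed_region" && is.null(region)) {
    stop("fixed_region modulation needs a region spec")
  }
  structure(list(mode = mode, factor = factor, region = region,
                 radius = radius, recenter_every = recenter_every,
                 k2n_factor = k2n_factor,
                 k2n_region_scale = k2n_region_scale),
            class = "rate_modulation")
}

#' Per-cell rate multipliers implied by a modulation
#'
#' @param modulation a [rate_modulation()] object.
#' @param mesh a [build_mesh()] result.
#' @param patch_center current patch-center cell index (patch_following
#'   mode), or `NULL` for no live patch (multipliers stay 1).
#' @return list with numeric vectors `mod0` (on `k0p`) and `mod2` (on
#'   `k2n`).
#' @export
apply_modulation_profile <- function(modulation, mesh, patch_center = NULL) {
  mod0 <- rep(1, mesh$n)
  mod2 <- rep(1, mesh$n)
  if (is.null(modulation) || modulation$mode == "none") {
    return(list(mod0 = mod0, mod2 = mod2))
  }
  if (modulation$mode == "fixed_region") {
    idx <- region_mask(mesh, modulation$region)
    mod0[idx] <- modulation$factor
    if (modulation$k2n_factor != 1) {
      idx2 <- scaled_region_mask(mesh, modulation)
      mod2[idx2] <- modulation$k2n_factor
    }
  } else {  # patch_following
    if (!is.null(patch_center)) {
      d <- geodesic_distances(mesh, patch_center)
      mod0[d <= modulation$radius] <- modulation$factor
      if (modulation$k2n_factor != 1) {
        r2 <- modulation$radius * sqrt(modulation$k2n_region_scale)
        mod2[d <= r2] <- modulation$k2n_factor
      }
    }
  }
  list(mod0 = mod0, mod2 = mod2)
}

scaled_region_mask <- function(mesh, modulation) {
  reg <- modulation$region
  if (reg$type == "geodesic_disc" && modulation$k2n_region_scale != 1) {
    reg$radius <- reg$radius * sqrt(modulation$k2n_region_scale)
  }
  region_mask(mesh, reg)
}

init_state <- function(params, mesh) {
  crd0 <- params$jRDp / params$r_RD
  list(
    crd = crd0 * (1 + params$init_rd_jitter * (2 * runif(mesh$n) - 1)),
    crt = crd0 * params$init_rt_frac * runif(mesh$n),
    cgap = numeric(mesh$n)
  )
}

#' Simulate Ras1 patch dynamics
#'
#' Integrates the three-field reaction-diffusion system (quasi-static GEF)
#' with forward Euler at `params$dt`, starting from the uniform Ras1-GDP
#' background (`jRDp / r_RD`) with small relative random perturbations, a
#' small random Ras1-GTP field and no membrane Gap1. Snapshots of all
#' fields are stored every `sample_stride` seconds.
#'
#' @param params a [ras1_params()] object.
#' @param mesh a [build_mesh()] result.
#' @param duration simulated time (s); at least 10 steps.
#' @param modulation optional [rate_modulation()].
#' @param seed integer seed for reproducibility (`NULL` = leave RNG alone).
#' @param sample_stride snapshot interval (s).
#' @param store_fields keep full per-cell snapshots (needed by the patch
#'   analytics; default `TRUE`).
#' @return an object of class `ras1_trajectory`: `times`, `max_crt`,
#'   `argmax_crt`, `ec`, snapshot matrices `crt`/`crd`/`cgap`
#'   (cells x frames), `clip_total`, the final state, `params`, `seed`.
#' @export
#' @examples
#' \donttest{
#' m <- build_mesh(mesh_spec(2, 6, 45, 40))
#' tr <- run_simulation(ras1_params(), m, duration = 600, seed = 1)
#' estimate_period(tr)
#' }
run_simulation <- function(params, mesh, duration, modulation = NULL,
                           seed = NULL, sample_stride = 1,
                           store_fields = TRUE) {
  stopifnot(inherits(params, "ras1_params"), duration >= 10 * params$dt)
  check_stability(mesh, params$dt,
                  list(C_RT = params$D_RT, C_RD = params$D_RD,
                       C_GAP = params$D_GAP))
  if (!is.null(seed)) set.seed(seed)
  state <- init_state(params, mesh)
  record_every <- max(1L, as.integer(round(sample_stride / params$dt)))
  pvec <- params_vector(params, mesh)

  follow <- !is.null(modulation) && modulation$mode == "patch_following"
  if (!follow) {
    mods <- apply_modulation_profile(modulation, mesh)
    n_steps <- as.integer(round(duration / params$dt))
    res <- integrate_patch_cpp(mesh$edges$i, mesh$edges$j,
                               mesh$edges$weight, mesh$area, pvec,
                               state$crt, state$crd, state$cgap,
                               mods$mod0, mods$mod2, params$dt, n_steps,
                               record_every, store_fields)
    out <- res
  } else {
    # integrate in recentering chunks; the modulated disc tracks the
    # current spatial maximum of Ras1-GTP
    chunk_steps <- max(1L, as.integer(round(modulation$recenter_every /
                                              params$dt)))
    n_chunks <- ceiling(duration / modulation$recenter_every)
    thr <- patch_threshold()
    center <- NULL
    acc <- NULL
    for (ch in seq_len(n_chunks)) {
      mods <- apply_modulation_profile(modulation, mesh, center)
      res <- integrate_patch_cpp(mesh$edges$i, mesh$edges$j,
                                 mesh$edges$weight, mesh$area, pvec,
                                 state$crt, state$crd, state$cgap,
                                 mods$mod0, mods$mod2, params$dt,
                                 chunk_steps, record_every, store_fields)
      state <- list(crt = res$CRT, crd = res$CRD, cgap = res$CGAP)
      center <- if (max(state$crt) > thr$abs_floor) which.max(state$crt)
                else NULL
      acc <- append_chunk(acc, res, (ch - 1) * modulation$recenter_every,
                          store_fields)
    }
    out <- acc
  }
  structure(list(
    times = out$times, max_crt = out$max_rt, argmax_crt = out$argmax_rt,
    ec = out$ec, crt = if (store_fields) out$fRT,
    crd = if (store_fields) out$fRD, cgap = if (store_fields) out$fGAP,
    clip_total = out$clip_total,
    final = list(crt = out$CRT, crd = out$CRD, cgap = out$CGAP),
    params = params, modulation = modulation, seed = seed,
    mesh = mesh, model = "quasi_static"
  ), class = "ras1_trajectory")
}

append_chunk <- function(acc, res, t_offset, store_fields) {
  drop1 <- if (is.null(acc)) seq_along(res$times) else -1L  # drop repeated t0
  chunk <- list(times = res$times[drop1] + t_offset,
                max_rt = res$max_rt[drop1],
                argmax_rt = res$argmax_rt[drop1],
                ec = res$ec[drop1],
                clip_total = res$clip_total,
                CRT = res$CRT, CRD = res$CRD, CGAP = res$CGAP)
  if (store_fields) {
    chunk$fRT <- res$fRT[, drop1, drop = FALSE]
    chunk$fRD <- res$fRD[, drop1, drop = FALSE]
    chunk$fGAP <- res$fGAP[, drop1, drop = FALSE]
  }
  if (is.null(acc)) return(chunk)
  acc$times <- c(acc$times, chunk$times)
  acc$max_rt <- c(acc$max_rt, chunk$max_rt)
  acc$argmax_rt <- c(acc$argmax_rt, chunk$argmax_rt)
  acc$ec <- c(acc$ec, chunk$ec)
  acc$clip_total <- acc$clip_total + chunk$clip_total
  acc$CRT <- chunk$CRT; acc$CRD <- chunk$CRD; acc$CGAP <- chunk$CGAP
  if (store_fields) {
    acc$fRT <- cbind(acc$fRT, chunk$fRT)
    acc$fRD <- cbind(acc$fRD, chunk$fRD)
    acc$fGAP <- cbind(acc$fGAP, chunk$fGAP)
  }
  acc
}

#' Expanded-model GEF binding parameters
#'
#' Parameters of the four-field model variant in which membrane GEF is an
#' explicit dynamical species with recruitment by single (`rho1`) and
#' paired (`rho2`) Ras1-GTP and first-order dissociation `r_GEF`. The
#' recruitment constants map onto the quasi-static coefficients via
#' `k1p = rho1 / r_GEF` and `k2p = rho2 / r_GEF`; when `rho1`/`rho2` are
#' `NULL` they are derived from the model parameters through this map.
#'
#' @param r_GEF GEF membrane dissociation rate (1/s).
#' @param rho1,rho2 recruitment rate constants; `NULL` = derive from
#'   `k1p`/`k2p`.
#' @param D_GEF GEF membrane diffusion coefficient (um^2/s); `NULL` = use
#'   the Ras1-GTP value.
#' @param dt integration step (s). The explicit GEF kinetics are stiff;
#'   the reference choice is 1e-5 s, and coarse meshes admit larger steps.
#' @return an `expanded_gef_params` object.
#' @export
expanded_gef_params <- function(r_GEF = 10, rho1 = NULL, rho2 = NULL,
                                D_GEF = NULL, dt = 1e-5) {
  stopifnot(r_GEF > 0, dt > 0)
  structure(list(r_GEF = r_GEF, rho1 = rho1, rho2 = rho2, D_GEF = D_GEF,
                 dt = dt), class = "expanded_gef_params")
}

#' Simulate the expanded model with explicit GEF binding kinetics
#'
#' @inheritParams run_simulation
#' @param gef_params an [expanded_gef_params()] object.
#' @return a `ras1_trajectory` (with `cgef` final field, `model =
#'   "expanded"`).
#' @export
run_expanded_simulation <- function(params, gef_params, mesh, duration,
                                    seed = NULL, sample_stride = 1,
                                    store_fields = TRUE) {
  stopifnot(inherits(params, "ras1_params"),
            inherits(gef_params, "expanded_gef_params"))
  rho1 <- if (is.null(gef_params$rho1)) params$k1p * gef_params$r_GEF
          else gef_params$rho1
  rho2 <- if (is.null(gef_params$rho2)) params$k2p * gef_params$r_GEF
          else gef_params$rho2
  d_gef <- if (is.null(gef_params$D_GEF)) params$D_RT else gef_params$D_GEF
  dt <- gef_params$dt
  check_stability(mesh, dt,
                  list(C_RT = params$D_RT, C_RD = params$D_RD,
                       C_GAP = params$D_GAP, C_GEF = d_gef))
  if (dt * gef_params$r_GEF > 0.5) {
    stop("unstable explicit step: dt = ", dt, " too large for r_GEF = ",
         gef_params$r_GEF, " (GEF dissociation)")
  }
  if (!is.null(seed)) set.seed(seed)
  state <- init_state(params, mesh)
  record_every <- max(1L, as.integer(round(sample_stride / dt)))
  n_steps <- as.integer(round(duration / dt))
  res <- integrate_expanded_cpp(mesh$edges$i, mesh$edges$j,
                                mesh$edges$weight, mesh$area,
                                params_vector(params, mesh), rho1, rho2,
                                gef_params$r_GEF, d_gef,
                                state$crt, state$crd, state$cgap,
                                numeric(mesh$n), dt, n_steps, record_every,
                                store_fields)
  structure(list(
    times = res$times, max_crt = res$max_rt, argmax_crt = res$argmax_rt,
    ec = res$ec, crt = if (store_fields) res$fRT, crd = NULL, cgap = NULL,
    cgef = if (store_fields) res$fGEF, clip_total = res$clip_total,
    final = list(crt = res$CRT, crd = res$CRD, cgap = res$CGAP,
                 cgef = res$CGEF),
    params = params, gef_params = gef_params, seed = seed, mesh = mesh,
    model = "expanded"
  ), class = "ras1_trajectory")
}

#' @export
print.ras1_trajectory <- function(x, ...) {
  cat(sprintf("Ras1 patch trajectory (%s model)\n",
              if (x$model == "expanded") "explicit-GEF" else
                "quasi-static GEF"))
  cat(sprintf("  %d frames over %.6g s, mesh of %d cells\n",
              length(x$times), max(x$times), x$mesh$n))
  cat(sprintf("  spatial max C_RT: last %.4g, peak %.4g um^-2\n",
              tail(x$max_crt, 1), max(x$max_crt)))
  cat(sprintf("  clipped mass %.3g molecules\n", x$clip_total))
  if (!is.null(x$seed)) cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' @export
summary.ras1_trajectory <- function(object, ...) {
  per <- estimate_period(object)
  lab <- classify_dynamics(object)
  cat("Dynamical regime:", lab, "\n")
  if (is.finite(per$period)) {
    cat(sprintf("Mean cycle period %.4g s over %d events\n", per$period,
                per$n_events))
  } else {
    cat("No recurrent cycling detected\n")
  }
  invisible(list(period = per, label = lab))
}

#' @export
plot.ras1_trajectory <- function(x, ...) {
  plot(x$times, x$max_crt, type = "l", xlab = "time (s)",
       ylab = expression("spatial max " * C[RT] * " (" * mu * m^-2 * ")"),
       ...)
  invisible(x)
}
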