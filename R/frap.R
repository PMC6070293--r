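#' FRAP model parameters
#'
#' `uniform_exchange_params()` describes a membrane species with uniform
#' cytoplasmic exchange: diffusion `D` (um^2/s), association flux `j_plus`
#' (um^-2 s^-1) and dissociation rate r (1/s); the pre-bleach steady
#' state is j_plus / r (or the uniform level `c0` when r = 0).
#'
#' `recruitment_params()` describes a species recruited at the cell tip by
#' a Gaussian source of total amplitude `A` (molecules/s) and width
#' `sigma` (um, arc distance to the tip), with dissociation rate r. At the
#' moment of bleaching the amplitude is multiplied by
#' `post_bleach_amp_factor` to model the bleached fraction of the
#' recruitable pool (0.5 for the fusion-focus protocol, 0.7 for the
#' half-tip protocol).
#'
#' @param D diffusion coefficient (um^2/s).
#' @param r membrane dissociation rate (1/s).
#' @param j_plus association flux (um^-2 s^-1).
#' @param c0 uniform pre-bleach level used when r = 0.
#' @param A Gaussian recruitment amplitude (molecules/s).
#' @param sigma Gaussian width (um); 0.4 for the mating fusion focus,
#'   0.8 for vegetative tips.
#' @param post_bleach_amp_factor amplitude multiplier applied at bleach.
#' @return parameter objects of class `uniform_exchange_params` /
#'   `recruitment_params`.
#' @name frap_params
NULL

#' @rdname frap_params
#' @export
uniform_exchange_params <- function(D, r = 0, j_plus = r, c0 = 1) {
  stopifnot(D >= 0, r >= 0, j_plus >= 0)
  structure(list(D = D, r = r, j_plus = j_plus, c0 = c0),
            class = "uniform_exchange_params")
}

#' @rdname frap_params
#' @export
recruitment_params <- function(D, r, A = 100, sigma = 0.4,
                               post_bleach_amp_factor = 0.5) {
  stopifnot(D >= 0, r >= 0, sigma > 0,
            post_bleach_amp_factor > 0, post_bleach_amp_factor <= 1)
  structure(list(D = D, r = r, A = A, sigma = sigma,
                 post_bleach_amp_factor = post_bleach_amp_factor),
            class = "recruitment_params")
}

#' FRAP protocol: bleach geometry, readout regions and acquisition
#'
#' @param bleach_region a [regions] spec zeroed at t = 0.
#' @param readout_regions named list of [regions] specs whose mean
#'   intensity is followed over time.
#' @param frame_interval acquisition interval (s).
#' @param slab_half_width half-width (um) of the confocal slab around the
#'   medial plane applied to readouts (`Inf` to disable).
#' @param n_prebleach_frames frames recorded before the bleach.
#' @param dt integration step (s).
#' @return a `frap_protocol` object.
#' @export
frap_protocol <- function(bleach_region, readout_regions,
                          frame_interval = 1, slab_half_width = 0.6,
                          n_prebleach_frames = 2, dt = 0.01) {
  stopifnot(inherits(bleach_region, "region_spec"), frame_interval > 0,
            length(readout_regions) >= 1,
            !is.null(names(readout_regions)), dt > 0)
  structure(list(bleach_region = bleach_region,
                 readout_regions = readout_regions,
                 frame_interval = frame_interval,
                 slab_half_width = slab_half_width,
                 n_prebleach_frames = n_prebleach_frames, dt = dt),
            class = "frap_protocol")
}

#' Standard FRAP protocols
#'
#' * `protocol_side_bleach(width)` — bleach a strip of the given axial
#'   width at the cell side over half the circumference (6.28 um for a
#'   radius-2 cell), readout of the bleached strip; the Ras1 protocol.
#' * `protocol_fusion_focus()` — bleach the whole front tip cap, readout
#'   of the middle of the tip and of the flanking sides; the mating-cell
#'   Gap1 protocol.
#' * `protocol_half_tip()` — bleach half of the front tip, readout of the
#'   bleached and non-bleached halves; the vegetative Gap1 protocol.
#'
#' @param width bleached strip axial width (um).
#' @param mesh_radius cylinder radius (um), fixes the half-circumference
#'   extent.
#' @param middle_arc arc radius of the tip "middle" readout (um).
#' @param side_arc outer arc radius of the "sides" readout (um).
#' @param ... passed to [frap_protocol()].
#' @return a `frap_protocol`.
#' @name frap_protocols
NULL

#' @rdname frap_protocols
#' @export
protocol_side_bleach <- function(width, mesh_radius = 2, ...) {
  reg <- region_side_strip(width, circ_extent = pi * mesh_radius)
  frap_protocol(reg, list(bleached = reg), ...)
}

#' @rdname frap_protocols
#' @export
protocol_fusion_focus <- function(middle_arc = 0.6, side_arc = 1.8, ...) {
  frap_protocol(
    region_tip_cap("front"),
    list(middle = region_spec("arc_band", lo = 0, hi = middle_arc),
         sides = region_spec("arc_band", lo = middle_arc, hi = side_arc),
         tip = region_tip_cap("front")),
    ...)
}

#' @rdname frap_protocols
#' @export
protocol_half_tip <- function(...) {
  frap_protocol(
    region_half_tip("front"),
    list(bleached = region_half_tip("front"),
         nonbleached = region_half_tip("front", phi_center = pi)),
    ...)
}

readout_cells <- function(mesh, protocol) {
  out <- lapply(protocol$readout_regions, function(reg) {
    idx <- if (reg$type == "arc_band") {
      which(mesh$s >= reg$lo & mesh$s < reg$hi)
    } else {
      region_mask(mesh, reg)
    }
    slab_restrict(mesh, idx, protocol$slab_half_width)
  })
  empty <- names(out)[lengths(out) == 0]
  if (length(empty)) {
    stop("readout region(s) ", paste(empty, collapse = ", "),
         " select no cells inside the confocal slab on this mesh; ",
         "widen slab_half_width or refine the mesh")
  }
  out
}

new_frap_trace <- function(times, intensity, sd = NULL, protocol, params,
                           prebleach, fields = NULL, cells = NULL,
                           mesh = NULL) {
  structure(list(times = times, intensity = intensity, sd = sd,
                 regions = colnames(intensity), protocol = protocol,
                 params = params, prebleach = prebleach, fields = fields,
                 cells = cells, mesh = mesh),
            class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  cat("FRAP recovery trace\n")
  cat(sprintf("  regions: %s\n", paste(x$regions, collapse = ", ")))
  cat(sprintf("  %d frames over %.6g s\n", length(x$times), max(x$times)))
  last <- round(100 * x$intensity[nrow(x$intensity), ], 1)
  cat(sprintf("  final recovery: %s\n",
              paste(sprintf("%s %.1f%%", x$regions, last), collapse = ", ")))
  invisible(x)
}

#' @export
plot.frap_trace <- function(x, ...) {
  matplot(x$times, x$intensity, type = "l", lty = 1,
          xlab = "time (s)", ylab = "normalized intensity", ...)
  legend("bottomright", legend = x$regions, lty = 1,
         col = seq_along(x$regions), bty = "n")
  invisible(x)
}

frap_frames <- function(protocol, duration) {
  record_every <- max(1L, as.integer(round(protocol$frame_interval /
                                             protocol$dt)))
  n_steps <- as.integer(round(duration / protocol$dt))
  list(record_every = record_every, n_steps = n_steps)
}

#' Simulate a FRAP experiment with uniform cytoplasmic exchange
#'
#' Integrates the linear transport model (surface diffusion plus uniform
#' membrane association/dissociation) from its uniform steady state,
#' zeroes the concentration on the bleach region at t = 0, and reports
#' per-region mean intensities normalized to the pre-bleach level, with
#' readouts restricted to the confocal slab.
#'
#' @param mesh a [build_mesh()] result.
#' @param params a [uniform_exchange_params()].
#' @param protocol a [frap_protocol()].
#' @param duration post-bleach time simulated (s).
#' @param store_fields keep per-cell snapshots (for profile fits).
#' @return a `frap_trace`.
#' @export
simulate_frap_uniform <- function(mesh, params, protocol, duration,
                                  store_fields = FALSE) {
  stopifnot(inherits(params, "uniform_exchange_params"))
  check_stability(mesh, protocol$dt, list(C = params$D))
  c0 <- if (params$r > 0) params$j_plus / params$r else params$c0
  C <- rep(c0, mesh$n)
  C[region_mask(mesh, protocol$bleach_region)] <- 0
  cells <- readout_cells(mesh, protocol)
  fr <- frap_frames(protocol, duration)
  res <- integrate_linear_cpp(mesh$edges$i, mesh$edges$j,
                              mesh$edges$weight, mesh$area, C, params$D,
                              params$r, rep(params$j_plus, mesh$n),
                              protocol$dt, fr$n_steps, fr$record_every,
                              cells, store_fields, 0)
  finish_trace(res, protocol, params, prebleach = rep(c0, length(cells)),
               cells = cells, mesh = mesh, store_fields = store_fields)
}

#' Simulate a FRAP experiment with Gaussian tip recruitment
#'
#' The species is recruited by a Gaussian source centered on the front
#' tip (total rate `A` molecules/s, width `sigma` in arc distance) and
#' dissociates uniformly. The pre-bleach state is the steady state of
#' this balance (run-in until the relative rate of change falls below
#' 1e-6/s); at t = 0 the bleach region is zeroed and the amplitude is
#' multiplied by `post_bleach_amp_factor`. By linearity the long-time
#' recovery level equals that factor.
#'
#' @inheritParams simulate_frap_uniform
#' @param params a [recruitment_params()].
#' @return a `frap_trace`.
#' @export
simulate_frap_recruitment <- function(mesh, params, protocol, duration,
                                      store_fields = FALSE) {
  stopifnot(inherits(params, "recruitment_params"), params$r > 0)
  check_stability(mesh, protocol$dt, list(C = params$D))
  src <- params$A / (2 * pi * params$sigma^2) *
    exp(-mesh$s^2 / (2 * params$sigma^2))
  cells <- readout_cells(mesh, protocol)
  # run-in to the pre-bleach steady state
  runin_steps <- min(2000000L,
                     as.integer(round(50 / params$r / protocol$dt)))
  ss <- integrate_linear_cpp(mesh$edges$i, mesh$edges$j,
                             mesh$edges$weight, mesh$area,
                             numeric(mesh$n), params$D, params$r, src,
                             protocol$dt, runin_steps,
                             1000L, cells, FALSE, 1e-6)
  if (!ss$converged) {
    warning("pre-bleach run-in did not reach the steady-state tolerance")
  }
  C <- ss$C
  prebleach <- vapply(cells, function(ix) mean(C[ix]), 0)
  C[region_mask(mesh, protocol$bleach_region)] <- 0
  fr <- frap_frames(protocol, duration)
  res <- integrate_linear_cpp(mesh$edges$i, mesh$edges$j,
                              mesh$edges$weight, mesh$area, C, params$D,
                              params$r,
                              src * params$post_bleach_amp_factor,
                              protocol$dt, fr$n_steps, fr$record_every,
                              cells, store_fields, 0)
  finish_trace(res, protocol, params, prebleach, cells, mesh, store_fields)
}

finish_trace <- function(res, protocol, params, prebleach, cells, mesh,
                         store_fields) {
  nf <- res$n_frames
  intensity <- sweep(res$trace[seq_len(nf), , drop = FALSE], 2,
                     prebleach, "/")
  colnames(intensity) <- names(cells)
  pre_t <- -rev(seq_len(protocol$n_prebleach_frames)) *
    protocol$frame_interval
  times <- c(pre_t, res$times[seq_len(nf)])
  intensity <- rbind(matrix(1, length(pre_t), ncol(intensity)), intensity)
  new_frap_trace(times = times, intensity = intensity, protocol = protocol,
                 params = params, prebleach = prebleach,
                 fields = if (store_fields) res$fields, cells = cells,
                 mesh = mesh)
}

#' Correct a recovery trace for acquisition photobleaching
#'
#' Fits an exponential decay `a * exp(-r_PB t)` to the
#' background-subtracted cytosolic signal by least squares and divides
#' the background-subtracted trace intensities by `exp(-r_PB t)`.
#'
#' @param times frame times (s).
#' @param raw raw intensities (vector or frames-by-regions matrix).
#' @param cytosol cytosolic reference intensities at the same frames.
#' @param background out-of-cell offset subtracted from both signals.
#' @param r_PB known decay constant (1/s); `NULL` to fit it.
#' @return list with `intensity` (corrected), `r_PB`, `background`.
#' @export
correct_photobleaching <- function(times, raw, cytosol, background = 0,
                                   r_PB = NULL) {
  raw <- as.matrix(raw)
  stopifnot(length(times) == nrow(raw), length(cytosol) == nrow(raw))
  cyt <- cytosol - background
  if (any(cyt <= 0)) {
    stop("cytosol signal is not positive after background subtraction")
  }
  if (is.null(r_PB)) {
    ssr <- function(r) {
      w <- exp(-r * times)
      a <- sum(cyt * w) / sum(w^2)
      sum((cyt - a * w)^2)
    }
    r_PB <- optimize(ssr, c(0, 10))$minimum
    if (ssr(0) <= ssr(r_PB)) r_PB <- 0   # constant cytosol
  }
  corrected <- (raw - background) / exp(-r_PB * times)
  list(intensity = corrected, r_PB = r_PB, background = background)
}

#' Grid-search fit of diffusion coefficient and exchange rate to FRAP data
#'
#' Simulates the chosen transport model over a (D, r) grid and compares
#' the normalized region-mean recovery curves with the measured traces
#' (sum of squared residuals over all traces, regions and post-bleach
#' frames; traces acquired with different protocols — for example small
#' and large bleached strips — are fitted jointly). Grid points whose
#' curves stay inside the per-frame standard-deviation band of every
#' trace form the acceptable set. Optionally the acceptable points are
#' re-ranked by SSR against stored spatial profiles (second narrowing
#' stage).
#'
#' @param traces a `frap_trace` or list of them (with `sd` matrices for
#'   band acceptance; traces must carry their protocols).
#' @param model_kind `"uniform"` or `"recruitment"`.
#' @param D_grid,r_grid numeric grids (um^2/s, 1/s). Defaults step 0.01
#'   in D and 0.005 in r.
#' @param mesh a [build_mesh()] result.
#' @param duration post-bleach duration to simulate (s); defaults to the
#'   trace length.
#' @param band `"pointwise"` (acceptance requires the curve inside the
#'   mean +/- sd band at every frame) or `"none"`.
#' @param profile_refine re-rank acceptable points against stored spatial
#'   profiles (requires traces simulated with `store_fields = TRUE`).
#' @param recruitment_template a [recruitment_params()] whose `A`,
#'   `sigma` and `post_bleach_amp_factor` are reused across the grid
#'   (recruitment fits only).
#' @param sim_cache optional environment reusing simulated grid curves
#'   across repeated fits that share protocols (e.g. replicate studies);
#'   curves are keyed by (D, r, trace position).
#' @return a `frap_fit`: data frame `grid` (D, r, ssr,
#'   `acceptable`), `best` (named vector), `out_of_band` flag.
#' @export
fit_frap_params <- function(traces, model_kind = c("uniform", "recruitment"),
                            D_grid = seq(0.01, 0.3, by = 0.01),
                            r_grid = seq(0, 0.05, by = 0.005),
                            mesh, duration = NULL,
                            band = c("pointwise", "none"),
                            profile_refine = FALSE,
                            recruitment_template = NULL,
                            sim_cache = NULL) {
  model_kind <- match.arg(model_kind)
  band <- match.arg(band)
  if (inherits(traces, "frap_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1, length(D_grid) >= 1, length(r_grid) >= 1)
  grid <- expand.grid(D = D_grid, r = r_grid)
  ssr <- numeric(nrow(grid))
  ok <- rep(TRUE, nrow(grid))
  pssr <- rep(NA_real_, nrow(grid))
  for (g in seq_len(nrow(grid))) {
    s_tot <- 0
    for (ti in seq_along(traces)) {
      tr <- traces[[ti]]
      dur <- if (is.null(duration)) max(tr$times) else duration
      key <- sprintf("%g_%g_%d", grid$D[g], grid$r[g], ti)
      sim <- if (!is.null(sim_cache) && !is.null(sim_cache[[key]])) {
        sim_cache[[key]]
      } else {
        s <- simulate_grid_point(mesh, model_kind, grid$D[g], grid$r[g],
                                 tr, dur, profile_refine,
                                 recruitment_template)
        if (!is.null(sim_cache)) sim_cache[[key]] <- s
        s
      }
      cmp <- match_frames(tr, sim)
      s_tot <- s_tot + sum((cmp$obs - cmp$sim)^2)
      if (band == "pointwise" && !is.null(tr$sd)) {
        dev <- abs(cmp$obs - cmp$sim) - cmp$sd
        if (any(dev > 0)) ok[g] <- FALSE
      }
      if (profile_refine && !is.null(tr$fields) && !is.null(sim$fields)) {
        k <- min(ncol(tr$fields), ncol(sim$fields))
        pssr[g] <- sum((tr$fields[, seq_len(k)] -
                          sim$fields[, seq_len(k)])^2, na.rm = TRUE)
      }
    }
    ssr[g] <- s_tot
  }
  out_of_band <- band == "pointwise" && !any(ok)
  cand <- if (out_of_band || band == "none") seq_len(nrow(grid)) else which(ok)
  score <- if (profile_refine && !all(is.na(pssr[cand]))) pssr[cand]
           else ssr[cand]
  best_i <- cand[which.min(score)]
  structure(list(
    grid = cbind(grid, ssr = ssr, acceptable = ok,
                 profile_ssr = pssr),
    best = c(D = grid$D[best_i], r = grid$r[best_i]),
    out_of_band = out_of_band, model_kind = model_kind
  ), class = "frap_fit")
}

simulate_grid_point <- function(mesh, model_kind, D, r, tr, duration,
                                store_fields, recruitment_template) {
  if (model_kind == "uniform") {
    p <- uniform_exchange_params(D = D, r = r, j_plus = r, c0 = 1)
    simulate_frap_uniform(mesh, p, tr$protocol, duration,
                          store_fields = store_fields)
  } else {
    tmpl <- if (!is.null(recruitment_template)) recruitment_template
            else tr$params
    p <- recruitment_params(D = D, r = r, A = tmpl$A, sigma = tmpl$sigma,
                            post_bleach_amp_factor =
                              tmpl$post_bleach_amp_factor)
    simulate_frap_recruitment(mesh, p, tr$protocol, duration,
                              store_fields = store_fields)
  }
}

match_frames <- function(tr, sim) {
  post <- which(tr$times >= 0)
  keep <- post[tr$times[post] <= max(sim$times)]
  idx <- match(round(tr$times[keep], 6), round(sim$times, 6))
  use <- !is.na(idx)
  list(obs = tr$intensity[keep[use], , drop = FALSE],
       sim = sim$intensity[idx[use], colnames(tr$intensity), drop = FALSE],
       sd = if (!is.null(tr$sd)) tr$sd[keep[use], , drop = FALSE] else
         matrix(Inf, sum(use), ncol(tr$intensity)))
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("FRAP grid fit (%s model), %d grid points\n", x$model_kind,
              nrow(x$grid)))
  cat(sprintf("  best: D = %.3g um^2/s, r = %.3g 1/s (SSR %.4g)\n",
              x$best["D"], x$best["r"],
              min(x$grid$ssr)))
  na <- sum(x$grid$acceptable)
  if (x$out_of_band) {
    cat("  no grid point lies inside the SD band (best-SSR point reported)\n")
  } else {
    cat(sprintf("  acceptable set: %d point(s) inside the SD band\n", na))
  }
  invisible(x)
}

#' @export
plot.frap_fit <- function(x, ...) {
  g <- x$grid
  plot(g$D[g$acceptable], g$r[g$acceptable], pch = 15,
       xlim = range(g$D), ylim = range(g$r),
       xlab = expression(D ~ (mu * m^2 / s)), ylab = "r (1/s)", ...)
  points(x$best["D"], x$best["r"], pch = 4, cex = 2)
  invisible(x)
}

#' Synthetic replicated FRAP traces with measurement noise
#'
#' Simulates the protocol once and adds independent Gaussian noise per
#' frame and per replicate cell, returning the replicate mean and
#' standard deviation — a synthetic stand-in for an averaged multi-cell
#' FRAP measurement.
#'
#' @param params model parameters ([uniform_exchange_params()] or
#'   [recruitment_params()]).
#' @param protocol a [frap_protocol()].
#' @param mesh a [build_mesh()] result.
#' @param duration post-bleach duration (s).
#' @param noise_sd Gaussian noise SD (normalized intensity units).
#' @param n_cells number of replicate cells.
#' @param seed RNG seed (deterministic output for a fixed seed).
#' @param base_trace optionally a precomputed noise-free `frap_trace`
#'   for these parameters (skips the simulation).
#' @return a `frap_trace` with `sd` and attribute `replicates`.
#' @export
synthetic_frap_traces <- function(params, protocol, mesh, duration,
                                  noise_sd = 0.05, n_cells = 5, seed = 1,
                                  base_trace = NULL) {
  stopifnot(noise_sd >= 0, n_cells >= 1)
  base <- if (!is.null(base_trace)) base_trace
  else if (inherits(params, "uniform_exchange_params")) {
    simulate_frap_uniform(mesh, params, protocol, duration)
  } else {
    simulate_frap_recruitment(mesh, params, protocol, duration)
  }
  set.seed(seed)
  nf <- nrow(base$intensity)
  nr <- ncol(base$intensity)
  reps <- array(rep(base$intensity, n_cells) +
                  rnorm(nf * nr * n_cells, sd = noise_sd),
                dim = c(nf, nr, n_cells))
  m <- apply(reps, c(1, 2), mean)
  s <- if (n_cells > 1) apply(reps, c(1, 2), sd) else
    matrix(0, nf, nr)
  dimnames(m) <- dimnames(base$intensity)
  dimnames(s) <- dimnames(base$intensity)
  out <- base
  out$intensity <- m
  out$sd <- s
  attr(out, "replicates") <- n_cells
  out
}

#' Read and write recovery traces as CSV
#'
#' Long format with columns `time_s`, `region`, `intensity_norm`, `sd`.
#'
#' @param trace a `frap_trace`.
#' @param path file path.
#' @param comment optional comment lines written as a `#` header.
#' @return `path` (writer) / a `frap_trace` without protocol metadata
#'   (reader).
#' @name frap_io
NULL

#' @rdname frap_io
#' @export
write_frap_csv <- function(trace, path, comment = NULL) {
  df <- data.frame(
    time_s = rep(trace$times, ncol(trace$intensity)),
    region = rep(trace$regions, each = nrow(trace$intensity)),
    intensity_norm = as.vector(trace$intensity),
    sd = if (!is.null(trace$sd)) as.vector(trace$sd) else NA_real_
  )
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname frap_io
#' @export
read_frap_csv <- function(path) {
  df <- read.csv(path, comment.char = "#")
  regions <- unique(df$region)
  times <- sort(unique(df$time_s))
  m <- sapply(regions, function(rg) {
    df$intensity_norm[df$region == rg][order(df$time_s[df$region == rg])]
  })
  s <- sapply(regions, function(rg) {
    df$sd[df$region == rg][order(df$time_s[df$region == rg])]
  })
  m <- matrix(m, ncol = length(regions),
              dimnames = list(NULL, regions))
  new_frap_trace(times = times, intensity = m,
                 sd = if (!all(is.na(s))) matrix(s, ncol = length(regions),
                                                 dimnames = list(NULL, regions)),
                 protocol = NULL, params = NULL,
                 prebleach = rep(1, length(regions)))
}
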