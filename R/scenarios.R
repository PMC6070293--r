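#' Built-in simulation scenarios
#'
#' Named, fully specified runs binding a mesh, parameters, modulation and
#' analyses. `list_scenarios()` returns the catalog;
#' [run_scenario()] executes one.
#'
#' @return named list of scenario configurations.
#' @export
list_scenarios <- function() {
  ref_mesh <- list(radius = 2, tip_to_tip_length = 6, n_axial = 45,
                   n_circ = 40)
  coarse_mesh <- list(radius = 2, tip_to_tip_length = 6, n_axial = 23,
                      n_circ = 20)
  base <- list(mesh = ref_mesh, params = list(), duration = 600, seed = 1,
               modulation = NULL, analyses = c("period", "classify"),
               sample_stride = 1)
  sc <- list(
    reference_exploration = base,
    gap1_null = modifyList(base, list(params = list(k2n = 0),
                                      duration = 300)),
    local_feedback_following = modifyList(base, list(
      modulation = list(mode = "patch_following", factor = 1.25,
                        radius = 1))),
    local_feedback_fixed = modifyList(base, list(
      duration = 900,
      modulation = list(mode = "fixed_region", factor = 1.2,
                        region = list(type = "geodesic_disc",
                                      cell = NA, radius = 1)))),
    stronger_gap_recruitment = modifyList(base, list(
      params = list(k3n = 500))),
    stronger_activation = modifyList(base, list(
      params = list(k0p = 0.032))),
    stabilized_narrow = modifyList(base, list(
      duration = 900,
      modulation = list(mode = "fixed_region", factor = 2,
                        k2n_factor = 3, k2n_region_scale = 1.5,
                        region = list(type = "geodesic_disc",
                                      cell = NA, radius = 1)))),
    expanded_gef_rgef10 = modifyList(base, list(
      model = "expanded", duration = 300,
      gef = list(r_GEF = 10, dt = 1e-5),
      long_running = TRUE)),
    expanded_gef_rgef10_coarse = modifyList(base, list(
      mesh = coarse_mesh, model = "expanded", duration = 300,
      gef = list(r_GEF = 10, dt = 2e-4)))
  )
  sc
}

resolve_scenario <- function(scenario) {
  if (is.character(scenario)) {
    cat_l <- list_scenarios()
    if (!scenario %in% names(cat_l)) {
      stop("unknown scenario: ", scenario, "; available: ",
           paste(names(cat_l), collapse = ", "))
    }
    cfg <- cat_l[[scenario]]
    cfg$name <- scenario
  } else if (is.list(scenario)) {
    cfg <- scenario
    if (is.null(cfg$name)) cfg$name <- "custom"
  } else {
    stop("scenario must be a name or a configuration list")
  }
  known <- c("name", "mesh", "params", "duration", "seed", "modulation",
             "analyses", "sample_stride", "model", "gef", "long_running",
             "out")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("invalid config key(s): ", paste(bad, collapse = ", "))
  cfg
}

config_modulation <- function(mod, mesh) {
  if (is.null(mod)) return(NULL)
  reg <- NULL
  if (!is.null(mod$region)) {
    r <- mod$region
    if (is.null(r$cell) || is.na(r$cell)) {
      # default: disc centered on the cell side at mid-length
      r$cell <- which.min(abs(mesh$z) + abs(angdiff(mesh$phi, 0)))
    }
    reg <- do.call(region_spec, r)
  }
  rate_modulation(mode = mod$mode,
                  factor = if (is.null(mod$factor)) 1 else mod$factor,
                  region = reg,
                  radius = if (is.null(mod$radius)) 1 else mod$radius,
                  recenter_every = if (is.null(mod$recenter_every)) 1
                                   else mod$recenter_every,
                  k2n_factor = if (is.null(mod$k2n_factor)) 1
                               else mod$k2n_factor,
                  k2n_region_scale = if (is.null(mod$k2n_region_scale)) 1
                                     else mod$k2n_region_scale)
}

#' Run a named or configured scenario
#'
#' Builds the mesh, runs the simulation (quasi-static or expanded model),
#' applies the requested analyses and writes CSV summaries plus a JSON
#' run manifest to `out_dir`. Deterministic for a fixed seed: identical
#' configuration and seed give byte-identical CSV summaries.
#'
#' @param scenario a name from [list_scenarios()], a configuration list,
#'   or a path to a YAML configuration file.
#' @param seed overrides the configured seed.
#' @param out_dir output directory (created if missing); `NULL` runs
#'   without writing files.
#' @return invisibly, a list with the `trajectory`, the analyses and the
#'   `manifest`.
#' @export
run_scenario <- function(scenario, seed = NULL, out_dir = NULL) {
  if (is.character(scenario) && file.exists(scenario) &&
      grepl("[.](yml|yaml|json)$", scenario)) {
    scenario <- if (grepl("json$", scenario)) {
      jsonlite::read_json(scenario, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(scenario)
    }
  }
  cfg <- resolve_scenario(scenario)
  if (!is.null(seed)) cfg$seed <- seed
  t_start <- Sys.time()
  mesh <- do.call(mesh_spec, cfg$mesh)
  mesh <- build_mesh(mesh)
  params <- do.call(ras1_params, as.list(cfg$params))
  modulation <- config_modulation(cfg$modulation, mesh)
  stride <- if (is.null(cfg$sample_stride)) 1 else cfg$sample_stride

  traj <- if (identical(cfg$model, "expanded")) {
    gp <- do.call(expanded_gef_params, as.list(cfg$gef))
    run_expanded_simulation(params, gp, mesh, cfg$duration,
                            seed = cfg$seed, sample_stride = stride)
  } else {
    run_simulation(params, mesh, cfg$duration, modulation = modulation,
                   seed = cfg$seed, sample_stride = stride)
  }

  analyses <- list()
  if ("period" %in% cfg$analyses) analyses$period <- estimate_period(traj)
  if ("classify" %in% cfg$analyses) {
    analyses$label <- classify_dynamics(traj)
  }
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- write_scenario_outputs(cfg, traj, analyses, out_dir)
  }
  manifest <- list(
    scenario = cfg$name,
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    version = as.character(packageVersion("ras1zone")),
    started = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = basename(files)
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(trajectory = traj, analyses = analyses,
                 manifest = manifest))
}

config_hash <- function(cfg) {
  cfg$out <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(cfg[order(names(cfg))]), collapse = ""), f)
  unname(tools::md5sum(f))
}

write_scenario_outputs <- function(cfg, traj, analyses, out_dir) {
  files <- character(0)
  f1 <- file.path(out_dir, "series.csv")
  write.csv(data.frame(time_s = traj$times, max_crt = traj$max_crt,
                       argmax_cell = traj$argmax_crt, ec = traj$ec),
            f1, row.names = FALSE)
  files <- c(files, f1)
  if (!is.null(analyses$period)) {
    f2 <- file.path(out_dir, "period.csv")
    p <- analyses$period
    write.csv(data.frame(period_s = p$period, n_events = p$n_events,
                         stable = p$stable), f2, row.names = FALSE)
    files <- c(files, f2)
  }
  if (!is.null(analyses$label)) {
    f3 <- file.path(out_dir, "classification.csv")
    write.csv(data.frame(scenario = cfg$name, label = analyses$label),
              f3, row.names = FALSE)
    files <- c(files, f3)
  }
  f4 <- file.path(out_dir, "final_state.vtk")
  write_mesh_vtk(traj$mesh, f4,
                 fields = list(crt = traj$final$crt, crd = traj$final$crd,
                               cgap = traj$final$cgap))
  c(files, f4)
}

#' Sweep one parameter across a base scenario
#'
#' Runs the base scenario once per value of `param` and aggregates the
#' period estimate and regime label. Per-value seeds derive
#' deterministically from the root seed; failures are recorded and the
#' sweep continues.
#'
#' @param param parameter path: a [ras1_params()] field name (e.g.
#'   `"r_GAP"`, `"rnoise"`).
#' @param values numeric values to sweep.
#' @param base base scenario (name or config list).
#' @param seed root seed.
#' @param replicates runs per value.
#' @param out_dir optional directory for the aggregated CSV.
#' @return data frame with `value`, `period`, `n_events`, `label`,
#'   `error`.
#' @export
sweep_scenario <- function(param, values, base = "reference_exploration",
                           seed = 1, replicates = 1, out_dir = NULL) {
  cfg <- resolve_scenario(base)
  if (!param %in% names(unclass(ras1_params()))) {
    stop("unknown parameter path: ", param)
  }
  rows <- lapply(seq_along(values), function(k) {
    res <- try({
      periods <- numeric(0)
      events <- 0L
      labels <- character(0)
      for (r in seq_len(replicates)) {
        cfg_k <- cfg
        cfg_k$params[[param]] <- values[k]
        cfg_k$seed <- child_seed(seed, k, r)
        out <- run_scenario(cfg_k)
        e <- out$analyses$period
        if (is.null(e)) e <- estimate_period(out$trajectory)
        if (is.finite(e$period)) periods <- c(periods, e$period)
        events <- events + e$n_events
        labels <- c(labels, if (!is.null(out$analyses$label))
          out$analyses$label else classify_dynamics(out$trajectory))
      }
      data.frame(value = values[k],
                 period = if (length(periods)) mean(periods) else NA_real_,
                 n_events = events,
                 label = names(sort(table(labels), decreasing = TRUE))[1],
                 error = NA_character_)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      data.frame(value = values[k], period = NA_real_, n_events = 0L,
                 label = "error",
                 error = conditionMessage(attr(res, "condition")))
    } else res
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out, file.path(out_dir, paste0("sweep_", param, ".csv")),
              row.names = FALSE)
  }
  out
}

#' Generate synthetic data fixtures
#'
#' Writes CSV fixtures with the generating parameters embedded as header
#' comments: synthetic FRAP recovery traces (`"frap_traces"`), synthetic
#' 1D cortical intensity profiles with planted patches
#' (`"cortical_profiles"`), or mesh exports (`"meshes"`). Deterministic
#' for a fixed seed.
#'
#' @param kind one of `"frap_traces"`, `"cortical_profiles"`, `"meshes"`.
#' @param seed RNG seed.
#' @param out output directory.
#' @param ... kind-specific settings: `frap_traces`: `D`, `r`,
#'   `noise_sd`, `n_cells`, `width`, `duration`, `mesh`;
#'   `cortical_profiles`: `n_patches`, `n_px`, `pixel_size`,
#'   `background_mean`, `background_sd`, `patch_amp`, `patch_width_px`.
#' @return character vector of files written.
#' @export
generate_fixtures <- function(kind = c("frap_traces", "cortical_profiles",
                                       "meshes"),
                              seed = 1, out = ".", ...) {
  kind <- match.arg(kind)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  opts <- list(...)
  switch(kind,
    frap_traces = {
      D <- opts$D %||% 0.15
      r <- opts$r %||% 0.001
      noise_sd <- opts$noise_sd %||% 0.05
      n_cells <- opts$n_cells %||% 5
      width <- opts$width %||% 4
      duration <- opts$duration %||% 60
      mesh <- opts$mesh %||% build_mesh(mesh_spec(2, 11, 41, 20))
      prot <- protocol_side_bleach(width, mesh$spec$radius)
      tr <- synthetic_frap_traces(uniform_exchange_params(D, r, j_plus = r),
                                  prot, mesh, duration, noise_sd, n_cells,
                                  seed)
      f <- file.path(out, "frap_traces.csv")
      write_frap_csv(tr, f, comment = sprintf(
        "synthetic FRAP fixture: D=%g um^2/s r=%g 1/s noise_sd=%g n_cells=%d strip=%g um seed=%d",
        D, r, noise_sd, n_cells, width, seed))
      f
    },
    cortical_profiles = {
      set.seed(seed)
      n_patches <- opts$n_patches %||% 3
      n_px <- opts$n_px %||% 300
      pixel_size <- opts$pixel_size %||% 0.13
      bg_mean <- opts$background_mean %||% 100
      bg_sd <- opts$background_sd %||% 8
      amp <- opts$patch_amp %||% 10 * bg_sd
      wpx <- opts$patch_width_px %||% 6
      prof <- rnorm(n_px, bg_mean, bg_sd * 0.5)
      centers <- sort(sample(seq(20, n_px - 20), n_patches))
      while (n_patches > 1 && min(diff(centers)) < 4 * wpx) {
        centers <- sort(sample(seq(20, n_px - 20), n_patches))
      }
      for (c0 in centers) {
        prof <- prof + amp * exp(-(seq_len(n_px) - c0)^2 / (2 * (wpx / 2)^2))
      }
      f <- file.path(out, "cortical_profile.csv")
      con <- file(f, "w")
      writeLines(paste0("# synthetic cortical profile: ", n_patches,
                        " planted patches at px ",
                        paste(centers, collapse = ","),
                        sprintf("; background %g +/- %g; pixel %g um; seed %d",
                                bg_mean, bg_sd, pixel_size, seed)), con)
      write.csv(data.frame(position_um = (seq_len(n_px) - 1) * pixel_size,
                           intensity = prof), con, row.names = FALSE)
      close(con)
      f
    },
    meshes = {
      mesh <- opts$mesh %||% build_mesh(mesh_spec(2, 6, 45, 40))
      f1 <- file.path(out, "membrane_mesh.ply")
      f2 <- file.path(out, "membrane_mesh.vtk")
      write_mesh_ply(mesh, f1)
      write_mesh_vtk(mesh, f2)
      c(f1, f2)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
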