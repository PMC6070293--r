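#' Model parameters for the Ras1 patch system
#'
#' Rate constants and pool sizes of the Ras1-GTP / Ras1-GDP / Gap1
#' reaction-diffusion system with GEF positive feedback. Defaults are the
#' reference parameter set for a mating cell (radius 2 um, tip-to-tip
#' 6 um):
#'
#' * `D_RT`, `D_RD`, `D_GAP` — membrane diffusion coefficients (um^2/s) of
#'   Ras1-GTP, Ras1-GDP and Gap1, estimated by FRAP.
#' * `r_RT`, `r_RD`, `r_GAP` — membrane dissociation rates (1/s).
#' * `k0p` — GEF-mediated activation rate constant (um^2/s).
#' * `k1p` (um^3), `k2p` (um^5) — linear and quadratic GEF-binding
#'   coefficients of the quasi-static positive feedback.
#' * `k1n` — spontaneous Ras1-GTP hydrolysis rate (1/s).
#' * `k2n` — Gap1-dependent hydrolysis rate constant (um^2/s).
#' * `k3n` — Gap1 recruitment amplitude (um^-2 s^-1).
#' * `Csat` — Ras1-GTP density at half-maximal Gap1 recruitment (um^-2);
#'   `h` — Hill exponent.
#' * `Ectot` — total cellular GEF pool (molecules).
#' * `jRDp` — uniform Ras1-GDP membrane association flux (um^-2 s^-1);
#'   the far-from-patch background density is `jRDp / r_RD` = 38 um^-2.
#' * `rnoise` — amplitude of random background activation (1/s), applied
#'   multiplicatively to the local Ras1-GDP density.
#' * `V` — cell volume (um^3); set to the mesh's enclosed volume when a
#'   mesh is supplied to the simulation functions and `V` is `NULL`.
#' * `dt` — forward-Euler integration step (s).
#'
#' @param ... named overrides of any default.
#' @return an object of class `ras1_params` (a named list).
#' @export
#' @examples
#' p <- ras1_params(k2n = 0)   # Gap1-dependent hydrolysis knocked out
#' p$k2n
ras1_params <- function(...) {
  p <- list(
    D_RT = 0.04, D_RD = 0.15, D_GAP = 0.2,
    r_RT = 0.02, r_RD = 0.001, r_GAP = 0.1,
    k0p = 0.02, k1p = 5, k2p = 1000,
    k1n = 0.002, k2n = 0.1, k3n = 100,
    Csat = 60, h = 2, Ectot = 100,
    jRDp = 0.038, rnoise = 0.002, V = NULL,
    dt = 0.01,
    init_rd_jitter = 0.05, init_rt_frac = 0.01
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(over)] <- over
  }
  num <- p[setdiff(names(p), "V")]
  stopifnot(all(vapply(num, is.numeric, TRUE)),
            all(unlist(num) >= 0), p$h >= 1, p$dt > 0)
  structure(p, class = "ras1_params")
}

#' @export
print.ras1_params <- function(x, ...) {
  cat("Ras1 patch model parameters\n")
  v <- unclass(x)
  v$V <- if (is.null(v$V)) "(mesh volume)" else v$V
  for (nm in names(v)) cat(sprintf("  %-14s %s\n", nm, format(v[[nm]])))
  invisible(x)
}

params_vector <- function(params, mesh) {
  v <- if (is.null(params$V)) mesh$enclosed_volume else params$V
  c(D_RT = params$D_RT, D_RD = params$D_RD, D_GAP = params$D_GAP,
    r_RT = params$r_RT, r_RD = params$r_RD, r_GAP = params$r_GAP,
    k0p = params$k0p, k1p = params$k1p, k2p = params$k2p,
    k1n = params$k1n, k2n = params$k2n, k3n = params$k3n,
    Csat = params$Csat, h = params$h, Ectot = params$Ectot,
    jRDp = params$jRDp, rnoise = params$rnoise, V = v)
}

# explicit-Euler diffusion stability check (Gershgorin bound on the
# discrete operator spectrum); errors naming the offending field
check_stability <- function(mesh, dt, D_named) {
  lim <- dt * unlist(D_named) * mesh$lap_rowmax
  if (any(lim > 1)) {
    worst <- names(which.max(lim))
    stop("unstable explicit step: dt = ", dt, " exceeds the diffusion ",
         "stability bound for ", worst, " (dt*D*lambda_max = ",
         signif(max(lim), 3), " > 1); reduce dt or coarsen the mesh")
  }
  invisible(TRUE)
}
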