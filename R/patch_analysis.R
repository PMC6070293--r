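#' Patch detection threshold policy
#'
#' A cell is "active" when its Ras1-GTP density exceeds
#' `max(abs_floor, rel_max * max(C_RT))`. The absolute floor suppresses
#' noise-level fluctuations: its default is five times the
#' noise-sustained Ras1-GTP background of the reference parameter set
#' (`rnoise/2 * C_RD / (k1n + r_RT)`, about 1.7 um^-2, so a floor near
#' 9 um^-2); the relative term tracks the current patch amplitude.
#'
#' Supra-threshold components closer than `merge_distance` (centroid to
#' centroid, as in the experimental counting rule) are counted as one
#' patch.
#'
#' @param abs_floor absolute density floor (um^-2).
#' @param rel_max fraction of the current spatial maximum.
#' @param merge_distance components closer than this are one patch (um).
#' @return a `patch_threshold` object.
#' @export
patch_threshold <- function(abs_floor = 5 * 1.73, rel_max = 0.25,
                            merge_distance = 0.26) {
  stopifnot(abs_floor >= 0, rel_max >= 0, rel_max <= 1,
            merge_distance >= 0)
  structure(list(abs_floor = abs_floor, rel_max = rel_max,
                 merge_distance = merge_distance),
            class = "patch_threshold")
}

#' Detect Ras1-GTP patches on the mesh
#'
#' Thresholds the Ras1-GTP field (see [patch_threshold()]) and labels
#' connected components of supra-threshold cells on the neighbor graph.
#'
#' @param crt per-cell Ras1-GTP density (um^-2).
#' @param mesh a [build_mesh()] result.
#' @param policy a [patch_threshold()].
#' @return list of patches, each with `cells`, `center` (argmax cell),
#'   `total` (molecules), `area` (um^2); empty list when nothing exceeds
#'   the threshold.
#' @export
detect_patches <- function(crt, mesh, policy = patch_threshold()) {
  stopifnot(length(crt) == mesh$n)
  thr <- max(policy$abs_floor, policy$rel_max * max(crt))
  act <- which(crt > thr)
  if (length(act) == 0) return(list())
  comp <- connected_components(mesh, act)
  comp <- merge_close_components(comp, mesh, policy$merge_distance)
  lapply(comp, function(cells) {
    list(cells = cells, center = cells[which.max(crt[cells])],
         total = sum(crt[cells] * mesh$area[cells]),
         area = sum(mesh$area[cells]))
  })
}

merge_close_components <- function(comp, mesh, merge_distance) {
  k <- length(comp)
  if (k < 2 || merge_distance <= 0) return(comp)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_len(k - 1)) {
    for (b in seq(a + 1, k)) {
      da <- mesh$centroid[comp[[a]], , drop = FALSE]
      db <- mesh$centroid[comp[[b]], , drop = FALSE]
      dmin <- sqrt(min(outer(rowSums(da^2), rowSums(db^2), "+") -
                         2 * tcrossprod(da, db)))
      if (dmin < merge_distance) parent[find(b)] <- find(a)
    }
  }
  roots <- vapply(seq_len(k), find, 1L)
  unname(lapply(split(seq_len(k), roots),
                function(ix) sort(unlist(comp[ix]))))
}

connected_components <- function(mesh, cells) {
  keep <- mesh$edges$i %in% cells & mesh$edges$j %in% cells
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(mesh$edges$i[keep]),
               to = as.character(mesh$edges$j[keep])),
    directed = FALSE,
    vertices = data.frame(name = as.character(cells)))
  cl <- igraph::components(g)
  split(cells, cl$membership)
}

#' Axial density profile through a cell
#'
#' Averages per-cell densities over a narrow strip along the long axis
#' through the azimuth of `through_cell`, grouped by generator ring
#' (matching axial position), ordered by arc distance to the front tip.
#'
#' @param fields named list of per-cell density vectors (for example
#'   `list(crt = ..., cgap = ...)`).
#' @param mesh a [build_mesh()] result.
#' @param through_cell cell index the strip passes through.
#' @param strip_width strip width (um).
#' @return data frame with `position` (arc distance to front tip, um) and
#'   one column per field.
#' @export
axial_profile <- function(fields, mesh, through_cell, strip_width = 0.2) {
  idx <- region_mask(mesh, region_axial_strip(through_cell, strip_width))
  ring <- round(mesh$s[idx], 6)
  ord <- order(ring)
  idx <- idx[ord]; ring <- ring[ord]
  grp <- match(ring, unique(ring))
  out <- data.frame(position = unique(ring))
  for (nm in names(fields)) {
    stopifnot(length(fields[[nm]]) == mesh$n)
    out[[nm]] <- as.numeric(tapply(fields[[nm]][idx], grp, mean))
  }
  out
}

#' Full width at half maximum of an axial profile peak
#'
#' Baseline (the median of the fifth of positions farthest from the peak)
#' is subtracted before measuring the width by linear interpolation of the
#' half-maximum crossings.
#'
#' @param profile data frame from [axial_profile()].
#' @param column which profile column to measure.
#' @return FWHM (um), `NA` if no peak.
#' @export
profile_fwhm <- function(profile, column = "crt") {
  x <- profile$position
  y <- profile[[column]]
  ipk <- which.max(y)
  far <- order(abs(x - x[ipk]), decreasing = TRUE)
  base <- median(y[far[seq_len(max(2, floor(length(y) / 5)))]])
  yy <- y - base
  if (yy[ipk] <= 0) return(NA_real_)
  half <- yy[ipk] / 2
  above <- yy >= half
  if (!any(above)) return(NA_real_)
  lo <- min(which(above)); hi <- max(which(above))
  x_lo <- if (lo > 1) {
    approx(yy[c(lo - 1, lo)], x[c(lo - 1, lo)], xout = half)$y
  } else x[lo]
  x_hi <- if (hi < length(x)) {
    approx(yy[c(hi, hi + 1)], x[c(hi, hi + 1)], xout = half)$y
  } else x[hi]
  x_hi - x_lo
}

#' Estimate the patch appearance/disappearance period
#'
#' Finds peaks of the spatial-maximum Ras1-GTP time series with prominence
#' of at least `prominence_frac` of the series range and reports the mean
#' peak-to-peak interval. A trajectory whose series settles (coefficient
#' of variation below 5% over the last half, with no qualifying peak
#' there) is flagged `stable`.
#'
#' @param trajectory a [run_simulation()] result (or a list with `times`
#'   and `max_crt`).
#' @param prominence_frac peak prominence threshold as a fraction of the
#'   series range.
#' @return list with `period` (s; `NA` when fewer than 2 events),
#'   `n_events`, `event_times`, and logical `stable`.
#' @export
estimate_period <- function(trajectory, prominence_frac = 0.5) {
  tt <- trajectory$times
  y <- trajectory$max_crt
  rng <- diff(range(y))
  idx <- if (rng > 0) peak_indices(y, prominence_frac * rng) else integer(0)
  event_times <- sort(tt[idx])
  half <- y[tt >= max(tt) / 2]
  stable <- sd(half) / max(mean(half), 1e-12) < 0.05 &&
    (length(event_times) == 0 || max(event_times) < max(tt) / 2)
  n <- length(event_times)
  period <- if (n >= 2) mean(diff(event_times)) else NA_real_
  list(period = period, n_events = n, event_times = event_times,
       stable = stable)
}

# local maxima with topographic prominence >= min_prom (classic
# higher-neighbor walk on a 1D series)
peak_indices <- function(y, min_prom) {
  n <- length(y)
  if (n < 3) return(integer(0))
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    lo_l <- y[i]
    for (j in seq(i - 1L, 1L)) {
      if (y[j] > y[i]) break
      if (y[j] < lo_l) lo_l <- y[j]
      if (j == 1L) break
    }
    lo_r <- y[i]
    for (j in seq(i + 1L, n)) {
      if (y[j] > y[i]) break
      if (y[j] < lo_r) lo_r <- y[j]
      if (j == n) break
    }
    keep[k] <- (y[i] - max(lo_l, lo_r)) >= min_prom
  }
  cand[keep]
}

trajectory_frame_stats <- function(trajectory,
                                   policy = patch_threshold()) {
  stopifnot(!is.null(trajectory$crt))
  mesh <- trajectory$mesh
  nf <- ncol(trajectory$crt)
  n_patches <- integer(nf)
  active_frac <- numeric(nf)
  center <- rep(NA_integer_, nf)
  med_cells <- rep(NA_real_, nf)
  has_crd <- !is.null(trajectory$crd)
  for (f in seq_len(nf)) {
    crt <- trajectory$crt[, f]
    p <- detect_patches(crt, mesh, policy)
    n_patches[f] <- length(p)
    # "active" = locally GTP-dominated; robust to changes in the total
    # membrane Ras1 budget between regimes
    active_frac[f] <- if (has_crd) {
      sum(mesh$area[crt > trajectory$crd[, f]]) / mesh$total_area
    } else {
      sum(mesh$area[crt > policy$abs_floor]) / mesh$total_area
    }
    if (length(p)) {
      main <- p[[which.max(vapply(p, `[[`, 0, "total"))]]
      center[f] <- main$center
      med_cells[f] <- median(vapply(p, function(q) length(q$cells), 0))
    }
  }
  data.frame(frame = seq_len(nf), time = trajectory$times,
             n_patches = n_patches, active_frac = active_frac,
             center = center, patch_cells = med_cells)
}

#' Classify the dynamical regime of a trajectory
#'
#' Rule-based labeling of the behaviors seen across parameter space:
#' `homogeneous_activation` (active area above 95% at late times),
#' `no_patch`, `stable_single_patch` (settled series, persistent single
#' patch, stationary center), `traveling_wave` (persistent patch with a
#' drifting center), `minimum_size_patch` (median patch of one Voronoi
#' cell), `multiple_patches`, `single_oscillating_occasional_two`, or
#' `single_oscillating`.
#'
#' @inheritParams estimate_period
#' @param policy a [patch_threshold()].
#' @return a single label (character).
#' @export
classify_dynamics <- function(trajectory, policy = patch_threshold()) {
  st <- trajectory_frame_stats(trajectory, policy)
  late <- st[st$time >= max(st$time) / 2, ]
  per <- estimate_period(trajectory)

  if (mean(late$active_frac) > 0.95) return("homogeneous_activation")
  if (all(st$n_patches == 0)) return("no_patch")

  present_frac <- mean(late$n_patches > 0)
  if (present_frac > 0.95 && per$stable) {
    centers <- late$center[!is.na(late$center)]
    drift <- center_drift(trajectory$mesh, centers)
    if (drift > 1.0) return("traveling_wave")
    if (mean(late$n_patches[late$n_patches > 0]) <= 1.3) {
      return("stable_single_patch")
    }
    return("multiple_patches")
  }
  if (median(st$patch_cells, na.rm = TRUE) <= 1) {
    return("minimum_size_patch")
  }
  with_patch <- st$n_patches[st$n_patches > 0]
  mean_count <- mean(with_patch)
  if (mean_count > 1.5) return("multiple_patches")
  if (per$n_events < 2 && mean(st$n_patches > 0) < 0.05) return("no_patch")
  if (mean_count > 1.1) return("single_oscillating_occasional_two")
  "single_oscillating"
}

center_drift <- function(mesh, centers) {
  if (length(centers) < 2) return(0)
  ref <- centers[[1]]
  d <- geodesic_distances(mesh, ref)
  max(d[centers])
}

#' Mean Ras1-GDP density far from the patch
#'
#' Time-average of `C_RD` over cells farther than `min_distance` (arc,
#' graph-geodesic) from the per-frame patch center.
#'
#' @param trajectory a [run_simulation()] result with stored fields.
#' @param min_distance exclusion radius around the patch center (um).
#' @return mean background density (um^-2).
#' @export
far_field_crd <- function(trajectory, min_distance = 2) {
  stopifnot(!is.null(trajectory$crd))
  mesh <- trajectory$mesh
  vals <- numeric(0)
  for (f in seq_len(ncol(trajectory$crd))) {
    ctr <- trajectory$argmax_crt[f]
    d <- geodesic_distances(mesh, ctr)
    far <- d > min_distance
    if (any(far)) vals <- c(vals, mean(trajectory$crd[far, f]))
  }
  mean(vals)
}

#' Scan a parameter grid and classify each point
#'
#' Runs one (or more) simulations per grid point and records the
#' dynamical-regime label, the estimated period and failures, for phase
#' diagrams over, e.g., (`k0p`, `k2n`) or (`Csat`, `k2n`).
#'
#' @param grid data frame whose columns name [ras1_params()] fields; one
#'   row per grid point.
#' @param base_params baseline [ras1_params()].
#' @param mesh a [build_mesh()] result.
#' @param duration simulated time per run (s).
#' @param replicates runs per grid point (majority label reported).
#' @param seed root seed; per-point child seeds derive deterministically.
#' @return `grid` with columns `label`, `period`, `n_events`, `error`.
#' @export
phase_scan <- function(grid, base_params, mesh, duration = 600,
                       replicates = 1, seed = 1) {
  labs <- character(nrow(grid))
  per <- rep(NA_real_, nrow(grid))
  nev <- integer(nrow(grid))
  err <- rep(NA_character_, nrow(grid))
  for (g in seq_len(nrow(grid))) {
    res <- try({
      labels <- character(replicates)
      periods <- rep(NA_real_, replicates)
      events <- integer(replicates)
      for (r in seq_len(replicates)) {
        p <- do.call(ras1_params,
                     modifyList(unclass(base_params),
                                as.list(grid[g, , drop = FALSE])))
        tr <- run_simulation(p, mesh, duration,
                             seed = child_seed(seed, g, r))
        labels[r] <- classify_dynamics(tr)
        e <- estimate_period(tr)
        periods[r] <- e$period
        events[r] <- e$n_events
      }
      list(label = names(sort(table(labels), decreasing = TRUE))[1],
           period = mean(periods, na.rm = TRUE), n_events = sum(events))
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      labs[g] <- "error"
      err[g] <- conditionMessage(attr(res, "condition"))
    } else {
      labs[g] <- res$label
      per[g] <- res$period
      nev[g] <- res$n_events
    }
  }
  cbind(grid, data.frame(label = labs, period = per, n_events = nev,
                         error = err))
}

child_seed <- function(root, ...) {
  idx <- c(...)
  (root * 7919 + sum(idx * 104729^(seq_along(idx) - 1))) %% 2147483647
}

#' Quantify patches in a 1D cortical intensity profile
#'
#' Applies the experimental counting rules to a line profile along the
#' cell cortex: contiguous runs of at least `min_region_px` pixels above
#' the background mean qualify as patches when their mean intensity
#' exceeds `background_mean + threshold_sd_mult * background_sd`;
#' qualifying regions separated by less than `merge_distance` are counted
#' as one patch; sizes are reported as the merged span times `pixel_size`.
#'
#' @param intensity numeric profile (intensity units, one value per
#'   pixel).
#' @param background_mean,background_sd cytoplasmic background statistics.
#' @param pixel_size pixel size (um).
#' @param threshold_sd_mult detection threshold in background SDs.
#' @param merge_distance maximum gap merged into one patch (um).
#' @param min_region_px minimum run length (pixels).
#' @return data frame with one row per patch: `start_px`, `end_px`,
#'   `size_um`, `mean_intensity`.
#' @export
quantify_profile_patches <- function(intensity, background_mean,
                                     background_sd, pixel_size = 0.13,
                                     threshold_sd_mult = 3,
                                     merge_distance = 0.26,
                                     min_region_px = 2) {
  if (!all(is.finite(intensity))) stop("profile contains non-finite values")
  empty <- data.frame(start_px = integer(0), end_px = integer(0),
                      size_um = numeric(0), mean_intensity = numeric(0))
  above <- intensity > background_mean
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts, end = ends)[r$values, , drop = FALSE]
  runs <- runs[runs$end - runs$start + 1 >= min_region_px, , drop = FALSE]
  if (nrow(runs) == 0) return(empty)
  thr <- background_mean + threshold_sd_mult * background_sd
  qual <- vapply(seq_len(nrow(runs)), function(k) {
    mean(intensity[runs$start[k]:runs$end[k]]) > thr
  }, TRUE)
  runs <- runs[qual, , drop = FALSE]
  if (nrow(runs) == 0) return(empty)
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (k in 2:nrow(runs)) {
      gap_um <- (runs$start[k] - merged$end[nrow(merged)] - 1) * pixel_size
      if (gap_um < merge_distance) {
        merged$end[nrow(merged)] <- runs$end[k]
      } else {
        merged <- rbind(merged, runs[k, ])
      }
    }
  }
  data.frame(
    start_px = merged$start, end_px = merged$end,
    size_um = (merged$end - merged$start + 1) * pixel_size,
    mean_intensity = vapply(seq_len(nrow(merged)), function(k) {
      mean(intensity[merged$start[k]:merged$end[k]])
    }, 0)
  )
}
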