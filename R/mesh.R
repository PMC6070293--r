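#' Specify a spherocylindrical membrane mesh
#'
#' Describes the closed surface used for all simulations: a cylinder of
#' radius `radius` with (hemi)spherical caps, discretized into Voronoi
#' polygons. Generator rings are spaced uniformly in meridian arc length
#' at the projected-axis pixel size (`tip_to_tip_length / n_axial`);
#' cylinder rings carry `n_circ` generators around the circumference and
#' cap rings carry counts proportional to their band area, with a single
#' generator at each pole, so polygon areas come out near-uniform
#' without any relaxation step.
#'
#' `tip_radius` allows blunter or sharper caps than the cylinder radius
#' (cap sphere of radius `tip_radius` meeting the cylinder rim); it is used
#' for the curvature-robustness study where the total surface area is held
#' fixed by adjusting the length (see [equal_area_length()]).
#'
#' @param radius cylinder radius (um).
#' @param tip_to_tip_length pole-to-pole cell length (um); must be at least
#'   twice the cap height.
#' @param n_axial number of generator rings along the long axis.
#' @param n_circ number of generators around the full circumference.
#' @param tip_radius cap sphere radius (um), defaults to `radius`.
#' @return an object of class `mesh_spec`.
#' @export
#' @examples
#' mesh_spec(radius = 2, tip_to_tip_length = 6, n_axial = 45, n_circ = 40)
mesh_spec <- function(radius = 2, tip_to_tip_length = 6, n_axial = 45,
                      n_circ = 40, tip_radius = radius) {
  stopifnot(radius > 0, tip_radius >= radius, n_axial >= 3, n_circ >= 3)
  h_cap <- cap_height(radius, tip_radius)
  if (tip_to_tip_length < 2 * h_cap) {
    stop("invalid geometry: tip_to_tip_length (", tip_to_tip_length,
         ") is shorter than two cap heights (", 2 * h_cap, ")")
  }
  structure(list(radius = radius, tip_to_tip_length = tip_to_tip_length,
                 n_axial = as.integer(n_axial), n_circ = as.integer(n_circ),
                 tip_radius = tip_radius),
            class = "mesh_spec")
}

cap_height <- function(radius, tip_radius) {
  tip_radius - sqrt(tip_radius^2 - radius^2)
}

#' Tip-to-tip length preserving total surface area under a tip-radius change
#'
#' Returns the tip-to-tip length of a spherocylinder with the given
#' `radius`/`tip_radius` whose total surface area equals that of a
#' reference spherocylinder (`reference_radius`, `reference_length`).
#' Tips blunter than the cylinder (`tip_radius > radius`) keep the
#' cylinder radius; tips sharper than the reference are obtained by
#' shrinking the cell radius itself (`radius = tip_radius < 2`), since a
#' cap sphere cannot be narrower than the cylinder it closes.
#'
#' @param radius cylinder radius (um).
#' @param tip_radius cap sphere radius (um), at least `radius`.
#' @param reference_radius,reference_length geometry of the
#'   equal-area reference cell (um).
#' @return tip-to-tip length (um).
#' @export
equal_area_length <- function(radius, tip_radius = radius,
                              reference_radius = 2,
                              reference_length = 6) {
  stopifnot(tip_radius >= radius)
  target <- 2 * pi * reference_radius *
    (reference_length - 2 * reference_radius) +
    4 * pi * reference_radius^2
  h_cap <- cap_height(radius, tip_radius)
  cap_area <- 2 * pi * tip_radius * h_cap
  l_cyl <- (target - 2 * cap_area) / (2 * pi * radius)
  if (is.na(l_cyl) || l_cyl < 0) {
    stop("no spherocylinder with this area and tip radius")
  }
  l_cyl + 2 * h_cap
}

# (rho, z) of the meridian point at arc distance s from the front pole
surface_at <- function(s, r, hc, rt, zc, s_cap, s_total) {
  if (s < s_cap) {
    th <- s / rt
    c(rho = rt * sin(th), z = zc + rt * cos(th))
  } else if (s < s_cap + 2 * hc) {
    c(rho = r, z = hc - (s - s_cap))
  } else {
    th <- (s_total - s) / rt
    c(rho = rt * sin(th), z = -(zc + rt * cos(th)))
  }
}

# meridian arc coordinate of an axial position z (arc from the front pole),
# for caps of radius rt meeting a cylinder of radius r spanning [-hc, hc]
arc_from_z <- function(z, r, hc, rt) {
  th_max <- asin(min(1, r / rt))
  s_cap <- rt * th_max
  zc <- hc - sqrt(max(0, rt^2 - r^2))
  s <- numeric(length(z))
  front <- z > hc
  back <- z < -hc
  mid <- !front & !back
  s[front] <- rt * acos(pmin(1, (z[front] - zc) / rt))
  s[mid] <- s_cap + (hc - z[mid])
  s[back] <- s_cap + 2 * hc + (rt * th_max -
    rt * acos(pmin(1, (-z[back] - zc) / rt)))
  s
}

#' Build the Voronoi surface mesh of a spherocylindrical membrane
#'
#' Places generator points per the [mesh_spec()], measures the Voronoi
#' tessellation of the closed surface (areas, centroids, neighbor adjacency,
#' shared-edge lengths) on a fine surface-of-revolution quadrature grid, and
#' assembles the finite-volume weights of the discrete Laplace-Beltrami
#' operator: `w_ij = edge_length / generator_distance`, shared symmetrically
#' between the two cells so that the operator is exactly conservative and
#' annihilates constants.
#'
#' @param spec a [mesh_spec()], or `NULL` to build from the remaining
#'   arguments.
#' @param ... arguments forwarded to [mesh_spec()] when `spec` is `NULL`.
#' @param quadrature number of quadrature rows/columns per generator ring /
#'   circumferential generator (controls measurement resolution).
#' @return an object of class `ras1_mesh` with components `area`,
#'   `centroid`, `s` (arc distance of each cell to the front tip), `phi`,
#'   `z`, `edges` (adjacency with Laplacian weights), `total_area`,
#'   `enclosed_volume` and `spec`.
#' @export
#' @examples
#' \donttest{
#' m <- build_mesh(mesh_spec(2, 6, 45, 40))
#' range(m$area)          # within the working range [0.017, 0.046]
#' m$enclosed_volume      # about 58.6 um^3
#' }
build_mesh <- function(spec = NULL, ..., quadrature = 24) {
  if (is.null(spec)) spec <- mesh_spec(...)
  stopifnot(inherits(spec, "mesh_spec"))
  r <- spec$radius; rt <- spec$tip_radius
  h_cap <- cap_height(r, rt)
  hc <- (spec$tip_to_tip_length - 2 * h_cap) / 2
  half_z <- hc + h_cap
  na <- spec$n_axial; nc <- spec$n_circ

  zc <- hc - sqrt(max(0, rt^2 - r^2))   # front cap sphere center
  th_max <- asin(min(1, r / rt))
  s_cap <- rt * th_max
  s_total <- 2 * s_cap + 2 * hc
  # target cell: axial arc spacing = projected-axis pixel size; on the
  # caps, rings continue at the same arc spacing with generator counts
  # proportional to the ring circumference (equal-area cells), plus one
  # pole generator per cap
  ds <- spec$tip_to_tip_length / na
  a0 <- ds * 2 * pi * r / nc
  cap_band_area <- function(sa, sb) {
    2 * pi * rt^2 * (cos(pmax(sa, 0) / rt) - cos(pmin(sb, s_cap) / rt))
  }
  band_area <- function(sa, sb) {
    mid <- function(x) pmin(pmax(x, 0), s_total)
    sa <- mid(sa); sb <- mid(sb)
    # split the band at the cap junctions and sum the exact pieces
    cuts <- cbind(pmin(sa, s_cap), pmin(sb, s_cap))
    a_front <- cap_band_area(cuts[, 1], cuts[, 2])
    cyl_lo <- pmin(pmax(sa, s_cap), s_cap + 2 * hc)
    cyl_hi <- pmin(pmax(sb, s_cap), s_cap + 2 * hc)
    a_cyl <- 2 * pi * r * (cyl_hi - cyl_lo)
    b_lo <- pmax(sa, s_cap + 2 * hc)
    b_hi <- pmax(sb, s_cap + 2 * hc)
    a_back <- cap_band_area(s_total - b_hi, s_total - b_lo)
    a_front + a_cyl + a_back
  }
  # one ring sequence pole-to-pole at uniform arc spacing; the rings
  # nearest each pole are replaced by the pole generators themselves
  m_rings <- max(5L, round(s_total / ds))
  dsr <- s_total / m_rings
  s_all <- (seq_len(m_rings) - 0.5) * dsr
  s_k <- s_all[-c(1L, m_rings)]
  lo <- c(s_k[1] / 2, (s_k[-1] + s_k[-length(s_k)]) / 2)
  hi <- c((s_k[-1] + s_k[-length(s_k)]) / 2,
          s_total - s_k[1] / 2)
  lo <- c(lo[1], lo[-1])
  ring_s <- s_k
  ring_n <- pmax(3L, as.integer(round(band_area(lo, hi) / a0 + 0.15)))

  gen_list <- vector("list", length(ring_s) + 2)
  gen_list[[1]] <- c(0, 0, zc + rt)                 # front pole
  for (k in seq_along(ring_s)) {
    srz <- surface_at(ring_s[k], r, hc, rt, zc, s_cap, s_total)
    nk <- ring_n[k]
    ph <- (seq_len(nk) - 0.5) * (2 * pi / nk)
    gen_list[[k + 1]] <- cbind(srz["rho"] * cos(ph), srz["rho"] * sin(ph),
                               srz["z"])
  }
  gen_list[[length(gen_list)]] <- c(0, 0, -(zc + rt))  # back pole
  gen <- do.call(rbind, gen_list)
  colnames(gen) <- c("x", "y", "z")
  gen_s <- arc_from_z(gen[, "z"], r, hc, rt)
  gen_s[1] <- 0
  gen_s[length(gen_s)] <- s_total
  gaps <- diff(c(0, sort(unique(gen_s)), s_total))
  s_window <- max(3 * s_total / na, 2.5 * max(gaps))
  n_s <- as.integer(quadrature * na)
  n_phi <- as.integer(max(16L * nc, 256L))

  meas <- measure_voronoi_cpp(gen, gen_s, r, hc, rt, n_s, n_phi, s_window)
  if (any(meas$area <= 0)) {
    stop("degenerate Voronoi tessellation: some cells received no area; ",
         "increase `quadrature`")
  }

  cen <- project_to_surface(meas$centroid, r, hc, rt, zc)
  s <- arc_from_z(cen[, 3], r, hc, rt)
  phi_c <- atan2(cen[, 2], cen[, 1])

  # two-point flux distance between GENERATORS: Voronoi edges are the
  # perpendicular bisectors of generator segments, so this pairing keeps
  # the flux approximation orthogonal
  d <- sqrt(rowSums((gen[meas$edge_i, , drop = FALSE] -
                       gen[meas$edge_j, , drop = FALSE])^2))
  edges <- data.frame(i = meas$edge_i, j = meas$edge_j,
                      len = meas$edge_len, weight = meas$edge_len / d,
                      dist = d)
  # drop spurious hairline contacts from quadrature staircasing
  keep <- edges$len > 0.05 * stats::median(edges$len)
  edges <- edges[keep, , drop = FALSE]

  vol <- enclosed_volume_estimate(cen, meas$area, r, hc, zc)
  rowsum_w <- numeric(nrow(gen))
  rs <- rowsum(c(edges$weight, edges$weight), c(edges$i, edges$j))
  rowsum_w[as.integer(rownames(rs))] <- rs[, 1]
  mesh <- structure(list(
    spec = spec, n = nrow(gen), generator = gen, centroid = cen,
    area = as.numeric(meas$area), s = s, phi = phi_c, z = cen[, 3],
    edges = edges, total_area = sum(meas$area), enclosed_volume = vol,
    analytic_area = 2 * pi * r * 2 * hc + 2 * (2 * pi * rt * h_cap),
    analytic_volume = pi * r^2 * 2 * hc +
      2 * (pi * h_cap^2 * (rt - h_cap / 3)),
    hc = hc, s_cap = rt * asin(min(1, r / rt)), s_total = s_total,
    lap_rowmax = max(rowsum_w / meas$area)
  ), class = "ras1_mesh")
  mesh
}

project_to_surface <- function(p, r, hc, rt, zc) {
  out <- p
  rho <- sqrt(p[, 1]^2 + p[, 2]^2)
  mid <- abs(p[, 3]) <= hc
  sc <- ifelse(rho > 0, r / rho, 1)
  out[mid, 1] <- p[mid, 1] * sc[mid]
  out[mid, 2] <- p[mid, 2] * sc[mid]
  for (sgn in c(1, -1)) {
    cap <- if (sgn > 0) p[, 3] > hc else p[, 3] < -hc
    if (!any(cap)) next
    v <- p[cap, , drop = FALSE]
    v[, 3] <- v[, 3] - sgn * zc
    nv <- sqrt(rowSums(v^2))
    v <- v * (rt / nv)
    v[, 3] <- v[, 3] + sgn * zc
    out[cap, ] <- v
  }
  out
}

enclosed_volume_estimate <- function(cen, area, r, hc, zc) {
  # divergence theorem: V = (1/3) sum_i area_i (c_i . n_i)
  n <- cen
  mid <- abs(cen[, 3]) <= hc
  rho <- sqrt(cen[, 1]^2 + cen[, 2]^2)
  n[mid, 1] <- cen[mid, 1] / rho[mid]
  n[mid, 2] <- cen[mid, 2] / rho[mid]
  n[mid, 3] <- 0
  for (sgn in c(1, -1)) {
    cap <- if (sgn > 0) cen[, 3] > hc else cen[, 3] < -hc
    if (!any(cap)) next
    v <- cen[cap, , drop = FALSE]
    v[, 3] <- v[, 3] - sgn * zc
    n[cap, ] <- v / sqrt(rowSums(v^2))
  }
  sum(area * rowSums(cen * n)) / 3
}

#' Apply the discrete Laplace-Beltrami operator
#'
#' Computes the surface Laplacian of a per-cell density field using the
#' mesh's conservative finite-volume weights. Exact for constants (returns
#' zero) and conservative: `sum(area * result)` vanishes to rounding for
#' every field.
#'
#' @param mesh a [build_mesh()] result.
#' @param field numeric vector of per-cell values.
#' @return numeric vector, the discrete Laplacian (1/um^2 times field units).
#' @export
apply_laplace_beltrami <- function(mesh, field) {
  stopifnot(inherits(mesh, "ras1_mesh"))
  if (length(field) != mesh$n) {
    stop("field length ", length(field), " does not match mesh size ", mesh$n)
  }
  if (!all(is.finite(field))) stop("field contains non-finite values")
  lap_apply_cpp(mesh$edges$i, mesh$edges$j, mesh$edges$weight,
                mesh$area, as.numeric(field))
}

#' @export
print.ras1_mesh <- function(x, ...) {
  sp <- x$spec
  cat("Voronoi spherocylinder membrane mesh\n")
  cat(sprintf("  radius %.3g um, tip-to-tip length %.3g um, tip radius %.3g um\n",
              sp$radius, sp$tip_to_tip_length, sp$tip_radius))
  cat(sprintf("  %d cells (%d rings x %d), %d adjacency edges\n",
              x$n, sp$n_axial, sp$n_circ, nrow(x$edges)))
  cat(sprintf("  total area %.4g um^2 (analytic %.4g), volume %.4g um^3 (analytic %.4g)\n",
              x$total_area, x$analytic_area, x$enclosed_volume,
              x$analytic_volume))
  cat(sprintf("  Voronoi cell areas %.4g - %.4g um^2\n",
              min(x$area), max(x$area)))
  invisible(x)
}

#' @export
summary.ras1_mesh <- function(object, ...) {
  print(object)
  invisible(list(area_range = range(object$area),
                 mean_area = mean(object$area),
                 n_edges = nrow(object$edges)))
}

mesh_graph <- function(mesh) {
  igraph::graph_from_data_frame(
    data.frame(from = mesh$edges$i, to = mesh$edges$j),
    directed = FALSE,
    vertices = data.frame(name = seq_len(mesh$n)))
}

#' Geodesic (graph) distances from one cell
#'
#' Shortest-path distances along the neighbor graph, with edge lengths equal
#' to the Euclidean distance between adjacent cell generator points. A good
#' approximation of surface geodesic distance at the mesh resolution.
#'
#' @param mesh a [build_mesh()] result.
#' @param from cell index.
#' @return numeric vector of distances (um) to every cell.
#' @export
geodesic_distances <- function(mesh, from) {
  g <- mesh_graph(mesh)
  as.numeric(igraph::distances(g, v = as.character(from),
                               weights = mesh$edges$dist))
}
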