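#' Membrane region specifications
#'
#' Regions select sets of Voronoi cells by centroid position and are used
#' for FRAP bleach/readout geometry and for localized rate modulation.
#'
#' * `region_side_strip()` — axial strip at the cell sides: cells within
#'   `width`/2 of `axial_center` along the axis and within a circumferential
#'   arc of total extent `circ_extent` centered on azimuth `phi_center`
#'   (use `Inf` for the full circumference).
#' * `region_tip_cap()` — every cell on the front or back cap.
#' * `region_half_tip()` — the half of a cap with `cos(phi - phi_center) > 0`.
#' * `region_geodesic_disc()` — cells within graph-geodesic distance
#'   `radius` of `cell` (radius 0 gives just `cell`).
#' * `region_axial_strip()` — strip of width `width` along the full long
#'   axis through the azimuth of `through_cell` (a pole-to-pole meridian
#'   band, used for axial density profiles).
#'
#' @param width strip width (um).
#' @param circ_extent circumferential arc length covered (um); `Inf` = all.
#' @param axial_center axial position of the strip center (um).
#' @param phi_center central azimuth (radians).
#' @param tip `"front"` or `"back"`.
#' @param cell,through_cell cell index.
#' @param radius geodesic radius (um).
#' @return a `region_spec` object for [region_mask()].
#' @name regions
NULL

region_spec <- function(type, ...) {
  structure(c(list(type = type), list(...)), class = "region_spec")
}

#' @rdname regions
#' @export
region_side_strip <- function(width, circ_extent = Inf, axial_center = 0,
                              phi_center = 0) {
  region_spec("side_strip", width = width, circ_extent = circ_extent,
              axial_center = axial_center, phi_center = phi_center)
}

#' @rdname regions
#' @export
region_tip_cap <- function(tip = c("front", "back")) {
  region_spec("tip_cap", tip = match.arg(tip))
}

#' @rdname regions
#' @export
region_half_tip <- function(tip = c("front", "back"), phi_center = 0) {
  region_spec("half_tip", tip = match.arg(tip), phi_center = phi_center)
}

#' @rdname regions
#' @export
region_geodesic_disc <- function(cell, radius) {
  region_spec("geodesic_disc", cell = cell, radius = radius)
}

#' @rdname regions
#' @export
region_axial_strip <- function(through_cell, width = 0.2) {
  region_spec("axial_strip", through_cell = through_cell, width = width)
}

angdiff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' Cells of a mesh falling in a region
#'
#' @param mesh a [build_mesh()] result.
#' @param region a region specification, see [regions].
#' @return integer vector of cell indices (possibly empty, with a warning).
#' @export
region_mask <- function(mesh, region) {
  stopifnot(inherits(mesh, "ras1_mesh"), inherits(region, "region_spec"))
  idx <- switch(region$type,
    side_strip = {
      keep <- abs(mesh$z - region$axial_center) <= region$width / 2
      if (is.finite(region$circ_extent)) {
        arc <- abs(angdiff(mesh$phi, region$phi_center)) * mesh$spec$radius
        keep <- keep & arc <= region$circ_extent / 2
      }
      which(keep)
    },
    tip_cap = {
      if (region$tip == "front") which(mesh$s < mesh$s_cap)
      else which(mesh$s > mesh$s_total - mesh$s_cap)
    },
    half_tip = {
      cap <- region_mask(mesh, region_tip_cap(region$tip))
      cap[cos(angdiff(mesh$phi[cap], region$phi_center)) > 0]
    },
    geodesic_disc = {
      d <- geodesic_distances(mesh, region$cell)
      which(d <= region$radius + 1e-12)
    },
    axial_strip = {
      phi0 <- mesh$phi[region$through_cell]
      rho <- sqrt(mesh$centroid[, 1]^2 + mesh$centroid[, 2]^2)
      off <- rho * sin(abs(angdiff(mesh$phi, phi0)))
      same_side <- cos(angdiff(mesh$phi, phi0)) > 0 | rho < region$width
      which(off <= region$width / 2 & same_side)
    },
    stop("unknown region type: ", region$type)
  )
  if (length(idx) == 0) warning("region selects no cells on this mesh")
  idx
}

# region restricted to the confocal slab |y| <= slab_half_width (medial
# plane = xz); NULL or Inf slab keeps everything
slab_restrict <- function(mesh, idx, slab_half_width) {
  if (is.null(slab_half_width) || !is.finite(slab_half_width)) return(idx)
  idx[abs(mesh$centroid[idx, 2]) <= slab_half_width]
}
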