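# Reporting zones and axisymmetric (2 pi r - weighted) zone averages.

#' Define a reporting zone
#'
#' An axisymmetric annular box: radii in [r_min, r_max], depths (from the
#' articular surface) in [z_min, z_max]. Defaults to the superficial impacted
#' zone used for viability reporting: top 200 um, r <= 2 mm (half of the
#' 4-mm-wide dissected impacted region).
#'
#' @param r_min,r_max Radial bounds (m).
#' @param z_min,z_max Depth bounds (m), measured from the surface.
#' @param name Optional label.
#' @return An object of class \code{zone_spec}.
#' @export
zone_spec <- function(r_min = 0, r_max = 2e-3, z_min = 0, z_max = 200e-6,
                      name = "superficial impacted") {
  stopifnot(r_max > r_min, z_max > z_min, r_min >= 0, z_min >= 0)
  structure(list(r_min = r_min, r_max = r_max, z_min = z_min, z_max = z_max,
                 name = name), class = "zone_spec")
}

#' Standard reporting zones
#'
#' \code{superficial_impacted}: top 200 um, r <= 2 mm (viability reporting).
#' \code{impacted_full}: full depth, r <= 2 mm (proteoglycan reporting).
#' \code{intact_full}: full-depth annulus 8 mm <= r <= 10 mm (intact
#' reference region, away from the impact).
#'
#' @param thickness Cartilage thickness (m).
#' @return Named list of \code{\link{zone_spec}} objects.
#' @export
standard_zones <- function(thickness = 1e-3) {
  list(
    superficial_impacted = zone_spec(0, 2e-3, 0, 200e-6, "superficial impacted"),
    superficial_intact = zone_spec(8e-3, 10e-3, 0, 200e-6, "superficial intact"),
    impacted_full = zone_spec(0, 2e-3, 0, thickness, "impacted full depth"),
    intact_full = zone_spec(8e-3, 10e-3, 0, thickness, "intact full depth")
  )
}

#' Volume-weighted zone average of a field quantity
#'
#' Axisymmetric mean: each sample point is weighted by \code{2 pi r} times its
#' cell area. Points are taken as centers of cells of size \code{dr x dz}; if
#' cell sizes are omitted they are inferred from the unique coordinate
#' spacings of a tensor-product grid.
#'
#' @param values Field values at the sample points.
#' @param r,z Point coordinates (m); \code{z} is depth from the surface.
#' @param zone A \code{\link{zone_spec}}.
#' @param dr,dz Optional cell sizes per point (m).
#' @return Scalar volume-weighted mean over the zone.
#' @export
zone_average <- function(values, r, z, zone, dr = NULL, dz = NULL) {
  stopifnot(length(values) == length(r), length(r) == length(z))
  inside <- r >= zone$r_min & r <= zone$r_max &
    z >= zone$z_min & z <= zone$z_max
  if (!any(inside))
    stop("empty zone: '", zone$name, "' contains no grid points")
  if (is.null(dr)) {
    ru <- sort(unique(r))
    dr_u <- if (length(ru) > 1) c(diff(ru), diff(ru)[length(ru) - 1]) else 1
    dr <- dr_u[match(r, ru)]
  }
  if (is.null(dz)) {
    zu <- sort(unique(z))
    dz_u <- if (length(zu) > 1) c(diff(zu), diff(zu)[length(zu) - 1]) else 1
    dz <- dz_u[match(z, zu)]
  }
  # exact annulus volume of the cell around each point, clipped at the axis
  w <- pi * ((r + dr / 2)^2 - pmax(r - dr / 2, 0)^2) * dz
  w <- w[inside]
  sum(w * values[inside]) / sum(w)
}

#' Relative proteoglycan content, impacted vs intact
#'
#' Ratio of the zone-averaged proteoglycan concentration in the impacted zone
#' to that in the intact reference zone.
#'
#' @param C_PG Proteoglycan field values.
#' @param r,z Point coordinates (m).
#' @param impacted_zone,intact_zone \code{\link{zone_spec}} objects.
#' @return Scalar ratio (1 = no relative loss).
#' @export
relative_pg <- function(C_PG, r, z, impacted_zone, intact_zone) {
  den <- zone_average(C_PG, r, z, intact_zone)
  if (den == 0) stop("intact-zone proteoglycan average is zero")
  zone_average(C_PG, r, z, impacted_zone) / den
}
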