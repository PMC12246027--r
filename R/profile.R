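# Depth-dependent composition and collagen architecture. Depth is the
# normalized coordinate zhat in [0, 1], 0 at the articular surface.

#' Depth profile of cartilage composition and collagen architecture
#'
#' Holds tabulated depth profiles of the initial fixed charge density
#' \code{c_FCD0(z)}, initial fluid fraction \code{n_fl0(z)} and collagen
#' density fraction \code{rho_z(z)}, plus the primary-fibril arcade angle.
#' Values between table points are linearly interpolated.
#'
#' The primary fibrils follow the classic arcade architecture: parallel to the
#' articular surface at the top, perpendicular to it (depth-aligned) at the
#' bottom. The angle between fibril and surface normal interpolates linearly
#' from 90 deg at \code{zhat = 0} to 0 deg at \code{zhat = 1} across
#' configurable superficial/middle/deep fractions.
#'
#' @param zhat Normalized depth grid in [0, 1] (0 = articular surface).
#' @param c_FCD0 Initial fixed charge density at \code{zhat} (mol m^-3), >= 0.
#' @param n_fl0 Initial fluid fraction at \code{zhat} (-), in (0, 1).
#' @param rho_z Collagen density fraction at \code{zhat} (-), in (0, 1).
#' @param zone_fractions Numeric length-3 (superficial, middle, deep) summing
#'   to 1; the arcade angle rotates from surface-parallel to depth-aligned
#'   across the middle zone.
#' @return An object of class \code{depth_profile} with interpolator functions
#'   \code{$fcd(z)}, \code{$nfl(z)}, \code{$rho(z)}, \code{$angle(z)} (radians
#'   from the surface-normal/depth axis).
#' @export
depth_profile <- function(zhat, c_FCD0, n_fl0, rho_z,
                          zone_fractions = c(0.15, 0.5, 0.35)) {
  stopifnot(length(zhat) >= 2, !is.unsorted(zhat),
            min(zhat) >= 0, max(zhat) <= 1,
            length(c_FCD0) == length(zhat), length(n_fl0) == length(zhat),
            length(rho_z) == length(zhat),
            all(c_FCD0 >= 0), all(n_fl0 > 0), all(n_fl0 < 1),
            all(rho_z > 0), all(rho_z < 1),
            length(zone_fractions) == 3,
            abs(sum(zone_fractions) - 1) < 1e-9)
  f_fcd <- stats::approxfun(zhat, c_FCD0, rule = 2)
  f_nfl <- stats::approxfun(zhat, n_fl0, rule = 2)
  f_rho <- stats::approxfun(zhat, rho_z, rule = 2)
  z1 <- zone_fractions[1]; z2 <- zone_fractions[1] + zone_fractions[2]
  f_angle <- function(z) {
    # angle from the depth axis: pi/2 (surface-parallel) -> 0 (depth-aligned)
    frac <- pmin(pmax((z - z1) / (z2 - z1), 0), 1)
    (1 - frac) * pi / 2
  }
  structure(list(zhat = zhat, c_FCD0 = c_FCD0, n_fl0 = n_fl0, rho_z = rho_z,
                 zone_fractions = zone_fractions,
                 fcd = f_fcd, nfl = f_nfl, rho = f_rho, angle = f_angle),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat("Cartilage depth profile (", length(x$zhat), " table points)\n", sep = "")
  cat(sprintf("  c_FCD0: %.3g..%.3g mol/m^3, n_fl0: %.3g..%.3g, rho_z: %.3g..%.3g\n",
              min(x$c_FCD0), max(x$c_FCD0), min(x$n_fl0), max(x$n_fl0),
              min(x$rho_z), max(x$rho_z)))
  invisible(x)
}

#' Fibril direction set at a given depth
#'
#' Primary fibrils: the two mirrored arcade directions in the r-z plane at the
#' arcade angle for this depth. Secondary fibrils: a fixed 13-direction
#' near-isotropic set (3 coordinate axes, 6 face diagonals, 4 body diagonals),
#' identical at every depth.
#'
#' @param zhat Normalized depth in [0, 1].
#' @param profile A \code{\link{depth_profile}}.
#' @return List with \code{primary} (2 x 3) and \code{secondary} (13 x 3) unit
#'   row vectors in (r, theta, z)-aligned local Cartesian axes.
#' @export
fibril_directions <- function(zhat, profile) {
  a <- profile$angle(zhat)  # angle from depth axis
  primary <- rbind(c(sin(a), 0, cos(a)),
                   c(-sin(a), 0, cos(a)))
  axes <- diag(3)
  face <- rbind(c(1, 1, 0), c(1, -1, 0), c(1, 0, 1),
                c(1, 0, -1), c(0, 1, 1), c(0, 1, -1)) / sqrt(2)
  body <- rbind(c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1)) / sqrt(3)
  list(primary = primary, secondary = rbind(axes, face, body))
}
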