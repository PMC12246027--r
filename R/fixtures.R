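# Synthetic inputs: strain fields and depth profiles that make every
# downstream module testable without the finite-element stage. The
# reference strain preset encodes the reference outcome of the impact
# stage (56% damaged cells in the superficial impacted zone at thresholds
# 0.40/1.50, i.e. a plateau shear strain of ~0.679 under the indenter).

#' Specification of a synthetic strain field
#'
#' @param pattern \code{"uniform"} (peak everywhere), \code{"radial_gaussian"}
#'   (plateau of width \code{plateau_radius} under the indenter, Gaussian
#'   radial decay beyond with half-width-at-half-maximum \code{width}), or
#'   \code{"depth_profile"} (radial_gaussian modulated linearly with depth).
#' @param peak Peak maximum shear strain (-), >= 0.
#' @param plateau_radius Radius of the constant-strain impacted column (m).
#' @param width Gaussian half-width of the radial decay (m).
#' @param nr,nz Grid dimensions.
#' @param radius,thickness Domain size (m).
#' @param noise_sd Standard deviation of multiplicative lognormal perturbation
#'   (0 = none).
#' @param seed RNG seed for the perturbation; recorded in the output header.
#' @return An object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(pattern = c("radial_gaussian", "uniform",
                                     "depth_profile"),
                         peak = 0.679, plateau_radius = 2.5e-3,
                         width = 2.5e-3, nr = 40, nz = 20,
                         radius = 12.5e-3, thickness = 1e-3,
                         noise_sd = 0, seed = 1L) {
  pattern <- match.arg(pattern)
  stopifnot(peak >= 0, width > 0, plateau_radius >= 0, noise_sd >= 0)
  structure(list(pattern = pattern, peak = peak,
                 plateau_radius = plateau_radius, width = width,
                 nr = nr, nz = nz, radius = radius, thickness = thickness,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic strain field
#'
#' Deterministic given the seed. The default (reference) spec has a
#' constant shear strain of 0.679 in the impacted column (r <= 2.5 mm, all
#' depths) decaying radially as a Gaussian with 2.5-mm half-width, so that
#' the superficial impacted zone (r <= 2 mm) has a damaged-cell fraction of
#' 0.56 at the reference thresholds.
#'
#' @param spec A \code{\link{fixture_spec}}.
#' @param path Optional path; if given, the field is also written as CSV (with
#'   the seed recorded in the header) and the path returned invisibly.
#' @return A \code{\link{strain_field}} (invisibly the path if \code{path}
#'   given).
#' @export
make_strain_fixture <- function(spec = fixture_spec(), path = NULL) {
  grid <- kinetics_grid(spec$nr, spec$nz, spec$radius, spec$thickness)
  r <- grid$r; z <- grid$z
  g <- switch(spec$pattern,
    uniform = rep(spec$peak, length(r)),
    radial_gaussian = spec$peak *
      ifelse(r <= spec$plateau_radius, 1,
             2^(-((r - spec$plateau_radius) / spec$width)^2)),
    depth_profile = spec$peak *
      ifelse(r <= spec$plateau_radius, 1,
             2^(-((r - spec$plateau_radius) / spec$width)^2)) *
      (1 - 0.3 * z / spec$thickness)
  )
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    g <- g * exp(stats::rnorm(length(g), 0, spec$noise_sd))
  }
  field <- strain_field(r, z, g, pore_pressure = 0, time = 0.5e-3)
  if (!is.null(path)) {
    con <- file(path, "w")
    writeLines(c(sprintf("# seed: %d", spec$seed),
                 sprintf("# pattern: %s peak: %.17g", spec$pattern, spec$peak),
                 sprintf("# time_s: %.17g", attr(field, "time"))), con)
    utils::write.csv(as.data.frame(field)[, .strain_cols], con,
                     row.names = FALSE)
    close(con)
    return(invisible(path))
  }
  field
}

#' Synthetic depth profile of composition and architecture
#'
#' Physiologically plausible mature-bovine-style profiles: fixed charge
#' density increasing smoothly with depth (120 to 250 mol m^-3), fluid
#' fraction decreasing (0.85 to 0.70), collagen density fraction higher at
#' the surface (0.22 to 0.16), arcade fibril angles from surface-parallel to
#' depth-aligned.
#'
#' @param n Number of depth table points.
#' @return A \code{\link{depth_profile}}.
#' @export
make_depth_profile_fixture <- function(n = 21) {
  zhat <- seq(0, 1, length.out = n)
  depth_profile(
    zhat = zhat,
    c_FCD0 = 120 + 130 * zhat^1.2,
    n_fl0 = 0.85 - 0.15 * zhat,
    rho_z = 0.22 - 0.06 * zhat
  )
}
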