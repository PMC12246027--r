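#' Constitutive material parameters
#'
#' Bundles the constants of the fibril-reinforced poroviscoelastic swelling
#' model: a compressible Neo-Hookean non-fibrillar matrix, tension-only
#' viscoelastic collagen fibrils, deformation-dependent Darcy permeability,
#' Donnan osmotic swelling and chemical-expansion stress. All values are SI
#' (Pa, m, s, mol m^-3, K).
#'
#' @param E_nf Young's modulus of the non-fibrillar matrix (Pa).
#' @param nu_nf Poisson's ratio of the non-fibrillar matrix (-), in (-1, 0.5).
#' @param E0 Initial (equilibrium) fibril network modulus (Pa).
#' @param E_eps Strain-dependent fibril network modulus (Pa).
#' @param eta Fibril damping coefficient (Pa s).
#' @param C Primary-to-secondary fibril stress ratio (-).
#' @param k0 Initial permeability (m^4 N^-1 s^-1).
#' @param M Strain-dependence exponent of the permeability (-).
#' @param a0 Chemical-expansion constant (Pa per mol m^-3, i.e. Pa m^3 mol^-1).
#' @param kappa Chemical-expansion exponent constant (m^3 mol^-1).
#' @param gamma_ext,gamma_int External/internal ion activity coefficients (-).
#' @param phi_ext,phi_int External/internal osmotic coefficients (-).
#' @param R Molar gas constant (J mol^-1 K^-1).
#' @param T Absolute temperature (K).
#' @param c_ext External salt concentration (mol m^-3); 150 is 0.15 M NaCl.
#' @return An object of class \code{material_params}.
#' @examples
#' mp <- material_params()
#' mp$E_nf
#' @export
material_params <- function(E_nf = 0.8e6, nu_nf = 0.15,
                            E0 = 10e6, E_eps = 1e9, eta = 1e9, C = 3.0,
                            k0 = 1.5e-15, M = 5,
                            a0 = 50.6, kappa = 3.95e-4,
                            gamma_ext = 0.92, gamma_int = 0.85,
                            phi_ext = 0.93, phi_int = 0.90,
                            R = 8.3145, T = 310, c_ext = 150) {
  stopifnot(E_nf > 0, nu_nf > -1, nu_nf < 0.5, E0 >= 0, E_eps >= 0,
            eta >= 0, C > 0, k0 > 0, T > 0, c_ext > 0)
  for (g in c(gamma_ext, gamma_int, phi_ext, phi_int))
    if (g <= 0 || g > 1) stop("activity/osmotic coefficients must lie in (0, 1]")
  structure(list(E_nf = E_nf, nu_nf = nu_nf, E0 = E0, E_eps = E_eps,
                 eta = eta, C = C, k0 = k0, M = M, a0 = a0, kappa = kappa,
                 gamma_ext = gamma_ext, gamma_int = gamma_int,
                 phi_ext = phi_ext, phi_int = phi_int,
                 R = R, T = T, c_ext = c_ext),
            class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat("Fibril-reinforced poroviscoelastic material parameters (SI units)\n")
  cat(sprintf("  non-fibrillar: E_nf = %.3g Pa, nu_nf = %.3g\n", x$E_nf, x$nu_nf))
  cat(sprintf("  fibrils: E0 = %.3g Pa, E_eps = %.3g Pa, eta = %.3g Pa s, C = %.3g\n",
              x$E0, x$E_eps, x$eta, x$C))
  cat(sprintf("  permeability: k0 = %.3g m^4/(N s), M = %.3g\n", x$k0, x$M))
  cat(sprintf("  swelling: a0 = %.3g, kappa = %.3g, c_ext = %.3g mol/m^3, T = %.1f K\n",
              x$a0, x$kappa, x$c_ext, x$T))
  invisible(x)
}

#' Cell-damage strain thresholds
#'
#' Maximum-shear-strain thresholds of the nonlinear cellular damage function:
#' no damage below \code{eps_init}, full damage above \code{eps_max}.
#'
#' @param eps_init Damage-initiation strain (-), default 0.40.
#' @param eps_max Full-damage strain (-), default 1.50.
#' @return An object of class \code{damage_thresholds}.
#' @export
damage_thresholds <- function(eps_init = 0.40, eps_max = 1.50) {
  stopifnot(eps_init > 0, eps_max > eps_init)
  structure(list(eps_init = eps_init, eps_max = eps_max),
            class = "damage_thresholds")
}

#' Reaction-diffusion kinetics parameters
#'
#' Rate constants and diffusivities of the post-impact biological model:
#' first-order death of damaged chondrocytes, NAC-mediated recovery of damaged
#' cells back to healthy, an exponential stimulus driving proteolytic-enzyme
#' release from damaged cells, Michaelis-Menten proteoglycan degradation by
#' those enzymes, and a baseline synthesis/turnover balance that keeps intact
#' tissue at steady state.
#'
#' Reference rates follow the study conditions: \code{k_death} = 6.9e-5 s^-1
#' (sensitivity range 4.6e-5 to 13.9e-5), \code{k_rec} = 0.53e-4
#' m^3 mol^-1 s^-1 (range 0.29e-4 to 0.53e-4), \code{alpha_aga} = 0.4e-5 s^-1.
#' \code{k_aga} is a calibrated scalar (see \code{\link{calibrate_kaga}});
#' the stimulus here is driven by the damaged-cell *fraction*, so the enzyme
#' units are arbitrary and absorbed into the calibration.
#'
#' @param k_death Damaged-to-dead cell death rate (s^-1).
#' @param k_rec Chondrocyte protection (recovery) rate (m^3 mol^-1 s^-1).
#' @param alpha_aga Stimulus rate constant (s^-1).
#' @param k_aga Stimulus constant for enzyme release (enzyme units per unit
#'   damaged fraction; calibrated).
#' @param D_NAC NAC diffusivity in cartilage (m^2 s^-1).
#' @param D_enz0 Proteolytic-enzyme diffusivity scale (m^2 s^-1); the local
#'   value is \code{D_enz0 * exp(-a_enz * C_PG/C_PG_init)}.
#' @param a_enz Exponent of the proteoglycan modulation of enzyme diffusivity.
#' @param K_M Michaelis constant of proteoglycan degradation (mol m^-3).
#' @param k_cat Catalytic rate of proteoglycan degradation
#'   (mol m^-3 s^-1 per enzyme unit).
#' @param k_enz_clear First-order enzyme clearance rate (s^-1).
#' @param k_turn Baseline proteoglycan turnover rate (s^-1); synthesis is
#'   \code{k_turn * C_PG_init * viable_fraction} so intact tissue is at steady
#'   state by construction.
#' @param literal_reported_dnac If TRUE, use the literal reported NAC diffusivity
#'   120e-6 m^2/s instead of the physically plausible default.
#' @return An object of class \code{kinetics_params}.
#' @export
kinetics_params <- function(k_death = 6.9e-5, k_rec = 0.53e-4,
                            alpha_aga = 0.4e-5, k_aga = 0,
                            D_NAC = 1.2e-10, D_enz0 = 1e-12, a_enz = 1,
                            K_M = 100, k_cat = 1e-3, k_enz_clear = 1e-5,
                            k_turn = 5e-8,
                            literal_reported_dnac = FALSE) {
  if (literal_reported_dnac) D_NAC <- 120e-6
  stopifnot(k_death >= 0, k_rec >= 0, alpha_aga >= 0, k_aga >= 0,
            D_NAC >= 0, D_enz0 >= 0, K_M > 0, k_cat >= 0,
            k_enz_clear >= 0, k_turn >= 0)
  structure(list(k_death = k_death, k_rec = k_rec, alpha_aga = alpha_aga,
                 k_aga = k_aga, D_NAC = D_NAC, D_enz0 = D_enz0, a_enz = a_enz,
                 K_M = K_M, k_cat = k_cat, k_enz_clear = k_enz_clear,
                 k_turn = k_turn),
            class = "kinetics_params")
}

#' @export
print.kinetics_params <- function(x, ...) {
  cat("Chondrocyte / matrix kinetics parameters\n")
  cat(sprintf("  k_death = %.3g 1/s, k_rec = %.3g m^3/(mol s), alpha_aga = %.3g 1/s\n",
              x$k_death, x$k_rec, x$alpha_aga))
  cat(sprintf("  k_aga = %.3g, D_NAC = %.3g m^2/s, D_enz0 = %.3g m^2/s\n",
              x$k_aga, x$D_NAC, x$D_enz0))
  cat(sprintf("  K_M = %.3g mol/m^3, k_cat = %.3g, k_enz_clear = %.3g 1/s, k_turn = %.3g 1/s\n",
              x$K_M, x$k_cat, x$k_enz_clear, x$k_turn))
  invisible(x)
}

#' NAC treatment schedule
#'
#' A single antioxidant bath: the NAC concentration on the free surfaces (top
#' and outer edge) steps from 0 to \code{bath_concentration} at time
#' \code{delay} after impact, stays there for \code{duration}, then returns to
#' 0 (media change; NAC diffuses freely back out).
#'
#' @param delay Time from impact to bath onset (s).
#' @param bath_concentration Bath NAC concentration (mol m^-3); 2 mM = 2.
#' @param duration Bath exposure time (s).
#' @return An object of class \code{treatment_schedule}.
#' @examples
#' treatment_schedule(delay = 4 * 3600)        # 4-h delayed, 1-day bath
#' treatment_schedule(bath_concentration = 0)  # untreated
#' @export
treatment_schedule <- function(delay = 0, bath_concentration = 2,
                               duration = 86400) {
  stopifnot(delay >= 0, bath_concentration >= 0, duration >= 0)
  structure(list(delay = delay, bath_concentration = bath_concentration,
                 duration = duration),
            class = "treatment_schedule")
}

#' Bath concentration at a given time
#'
#' @param schedule A \code{\link{treatment_schedule}}.
#' @param t Time after impact (s), vectorized.
#' @return NAC bath concentration(s) (mol m^-3).
#' @export
bath_concentration_at <- function(schedule, t) {
  ifelse(t >= schedule$delay & t < schedule$delay + schedule$duration,
         schedule$bath_concentration, 0)
}
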