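# Material-point implementation of the fibril-reinforced poroviscoelastic
# swelling model. All operations work on plain numeric 3x3 tensors / scalars
# so they can be verified standalone against closed forms and numerical
# differentiation, independently of the finite-element stage.

#' Cauchy stress of the compressible Neo-Hookean non-fibrillar matrix
#'
#' \deqn{\sigma_{nf} = \frac{E_{nf}}{3(1-2\nu_{nf})}\frac{\ln J}{J} I +
#'       \frac{E_{nf}}{2(1+\nu_{nf})}\frac{1}{J}(F F^T - J^{2/3} I)}
#' with \eqn{J = \det F}. The stress vanishes in the reference configuration
#' and under pure rotations.
#'
#' @param F Deformation gradient, numeric 3x3 matrix with \code{det(F) > 0}.
#' @param params A \code{\link{material_params}} object.
#' @return Symmetric 3x3 Cauchy stress tensor (Pa).
#' @export
neo_hookean_stress <- function(F, params) {
  stopifnot(is.matrix(F), all(dim(F) == c(3, 3)))
  J <- det(F)
  if (!is.finite(J) || J <= 0)
    stop("invalid deformation: det(F) must be positive, got ", format(J))
  K3 <- params$E_nf / (3 * (1 - 2 * params$nu_nf))
  G  <- params$E_nf / (2 * (1 + params$nu_nf))
  B  <- F %*% t(F)
  S  <- K3 * log(J) / J * diag(3) + (G / J) * (B - J^(2 / 3) * diag(3))
  (S + t(S)) / 2
}

# Strain energy density consistent with neo_hookean_stress; used by the test
# suite's finite-difference oracle but exported for transparency.
#' Neo-Hookean strain energy density
#'
#' The energy whose Cauchy stress is \code{\link{neo_hookean_stress}}:
#' \eqn{W = G/2 (I_1 - 3) - 3G/2 (J^{2/3} - 1) + K/2 (\ln J)^2} with
#' \eqn{K = E_{nf}/(3(1-2\nu))} and \eqn{G = E_{nf}/(2(1+\nu))}.
#'
#' @inheritParams neo_hookean_stress
#' @return Scalar energy density (Pa).
#' @export
neo_hookean_energy <- function(F, params) {
  J <- det(F)
  if (J <= 0) stop("invalid deformation: det(F) must be positive")
  K3 <- params$E_nf / (3 * (1 - 2 * params$nu_nf))
  G  <- params$E_nf / (2 * (1 + params$nu_nf))
  I1 <- sum(F * F)
  G / 2 * (I1 - 3) - 3 * G / 2 * (J^(2 / 3) - 1) + K3 / 2 * log(J)^2
}

#' Implicit update of the viscoelastic fibril stress
#'
#' Integrates the tension-only nonlinear viscoelastic fibril relation (a linear
#' spring of modulus \code{E0} in parallel with a Maxwell branch whose spring
#' is quadratic, \eqn{\sigma_s = E_\epsilon \epsilon_s^2}, in series with a
#' dashpot \eqn{\eta}):
#' \deqn{\sigma_f = -\frac{\eta}{2\sqrt{E_\epsilon(\sigma_f - E_0\epsilon_f)}}
#'   \dot\sigma_f + E_0\epsilon_f + \Big(\eta +
#'   \frac{\eta E_0}{2\sqrt{E_\epsilon(\sigma_f - E_0\epsilon_f)}}\Big)
#'   \dot\epsilon_f, \quad \epsilon_f \ge 0}
#' and \eqn{\sigma_f = 0} for \eqn{\epsilon_f < 0}. A backward-Euler step with
#' Newton iteration is taken on the overstress
#' \eqn{u = \sigma_f - E_0 \epsilon_f \ge 0}; the radicand
#' \eqn{E_\epsilon u} is clamped at \code{1e-12 * E_eps * E0} to stay regular
#' at the elastic limit. The instantaneous (fast-rate) response of this model
#' is \eqn{E_0\epsilon + E_\epsilon \epsilon^2}; the slow-rate limit is
#' \eqn{E_0\epsilon}.
#'
#' @param eps_new Fibril strain at the end of the step (-).
#' @param state List with history \code{sigma_f} and \code{eps_f} at the start
#'   of the step (use \code{fibril_history()} for a virgin state).
#' @param params A \code{\link{material_params}} object.
#' @param dt Time-step size (s), positive.
#' @return Updated state list with fields \code{sigma_f} and \code{eps_f}.
#' @seealso \code{\link{fibril_ramp}} for integrating a whole strain ramp.
#' @export
fibril_stress_update <- function(eps_new, state, params, dt) {
  stopifnot(dt > 0)
  if (eps_new < 0)  # tension-only: compressed fibril carries nothing
    return(list(sigma_f = 0, eps_f = eps_new))
  if (params$eta == 0)  # dashpot-free: branch carries nothing
    return(list(sigma_f = params$E0 * eps_new, eps_f = eps_new))
  E0 <- params$E0; Ee <- params$E_eps; eta <- params$eta
  u_old <- max(state$sigma_f - E0 * state$eps_f, 0)
  deps <- (eps_new - max(state$eps_f, 0)) / dt
  clamp <- 1e-12 * Ee * E0
  # residual of backward Euler on u' = (2 sqrt(Ee u)/eta) (eta deps - u)
  g <- function(u) {
    s <- sqrt(max(Ee * u, clamp))
    u - u_old - dt * (2 * s / eta) * (eta * deps - u)
  }
  # bracket: u stays between 0 and max(u_old, instantaneous Ee*deps^2*dt^2 ...)
  hi <- max(u_old, abs(eta * deps), Ee * eps_new^2, clamp / Ee) * 2 + 1
  lo <- 0
  if (g(lo) > 0) {
    u_new <- 0
  } else {
    while (g(hi) < 0) hi <- hi * 4
    u_new <- stats::uniroot(g, c(lo, hi), tol = 1e-12 * max(1, hi))$root
  }
  list(sigma_f = E0 * eps_new + max(u_new, 0), eps_f = eps_new)
}

#' Virgin fibril history
#'
#' @return A zero-stress, zero-strain fibril history list.
#' @export
fibril_history <- function() list(sigma_f = 0, eps_f = 0)

#' Integrate the fibril model along a constant-rate strain ramp
#'
#' Convenience driver for \code{\link{fibril_stress_update}}: ramps the fibril
#' strain from 0 to \code{eps_end} at \code{rate} using \code{n} implicit
#' steps and returns the final stress.
#'
#' @param eps_end Final fibril strain (-).
#' @param rate Strain rate (s^-1), positive.
#' @param params A \code{\link{material_params}} object.
#' @param n Number of implicit steps.
#' @return Final fibril stress (Pa).
#' @export
fibril_ramp <- function(eps_end, rate, params, n = 400) {
  stopifnot(rate > 0, eps_end >= 0)
  dt <- (eps_end / rate) / n
  st <- fibril_history()
  for (i in seq_len(n))
    st <- fibril_stress_update(i * eps_end / n, st, params, dt)
  st$sigma_f
}

#' Total fibril network Cauchy stress
#'
#' Sums tension-only fibril contributions over a direction set:
#' \eqn{\rho_z C \sigma_f e_f \otimes e_f} for primary fibrils and
#' \eqn{\rho_z \sigma_f e_f \otimes e_f} for secondary fibrils, where the
#' scalar fibril stress is evaluated from the fibril strain
#' \eqn{\epsilon_f = e_f \cdot E e_f} along each direction. This quasi-static
#' evaluator uses the equilibrium response \eqn{\sigma_f = E_0\epsilon_f} (the
#' slow-rate limit of the viscoelastic relation); pass
#' \code{instantaneous = TRUE} for the fast-rate curve
#' \eqn{E_0\epsilon + E_\epsilon\epsilon^2}.
#'
#' @param E_GL Green-Lagrange strain tensor, symmetric 3x3 (-); fibril strains
#'   are taken as the normal strains along the directions.
#' @param directions List with \code{primary} (n x 3 matrix of unit vectors)
#'   and \code{secondary} (m x 3 matrix); see \code{\link{fibril_directions}}.
#' @param rho_z Collagen density fraction at the evaluation point (-).
#' @param params A \code{\link{material_params}} object.
#' @param instantaneous Use the fast-rate fibril curve (default FALSE).
#' @return Symmetric 3x3 fibril network Cauchy stress (Pa).
#' @export
fibril_network_stress <- function(E_GL, directions, rho_z, params,
                                  instantaneous = FALSE) {
  stopifnot(is.matrix(E_GL), all(dim(E_GL) == c(3, 3)))
  sig <- matrix(0, 3, 3)
  add <- function(sig, dirs, weight) {
    if (is.null(dirs) || nrow(dirs) == 0) return(sig)
    for (i in seq_len(nrow(dirs))) {
      e <- dirs[i, ]
      eps_f <- drop(e %*% E_GL %*% e)
      if (eps_f <= 0) next  # tension-only
      sf <- params$E0 * eps_f
      if (instantaneous) sf <- sf + params$E_eps * eps_f^2
      sig <- sig + weight * rho_z * sf * tcrossprod(e)
    }
    sig
  }
  sig <- add(sig, directions$primary, params$C)
  sig <- add(sig, directions$secondary, 1)
  (sig + t(sig)) / 2
}

#' Deformation-dependent permeability
#'
#' \eqn{k = k_0 J^M}.
#'
#' @param J Volumetric deformation det(F) (-), positive.
#' @param params A \code{\link{material_params}} object.
#' @return Permeability (m^4 N^-1 s^-1), vectorized over \code{J}.
#' @export
permeability <- function(J, params) {
  if (any(!is.finite(J)) || any(J <= 0))
    stop("invalid deformation: J must be positive")
  params$k0 * J^params$M
}

#' Current fixed charge density under deformation
#'
#' Fixed charges are matrix-bound and conserved, so compression concentrates
#' them in the shrinking fluid volume:
#' \eqn{c_{FCD} = c_{FCD,0}\, n_{fl,0} / (n_{fl,0} - 1 + J)}.
#'
#' @param J Volumetric deformation (-).
#' @param c_FCD0 Initial fixed charge density (mol m^-3 of fluid), >= 0.
#' @param n_fl0 Initial fluid fraction (-), in (0, 1).
#' @return Current fixed charge density (mol m^-3), vectorized.
#' @export
fcd_current <- function(J, c_FCD0, n_fl0) {
  stopifnot(all(c_FCD0 >= 0), all(n_fl0 > 0), all(n_fl0 < 1))
  den <- n_fl0 - 1 + J
  if (any(den <= 0))
    stop("invalid deformation: pore space collapsed (n_fl0 - 1 + J <= 0)")
  c_FCD0 * n_fl0 / den
}

#' Mobile anion concentration from ideal Donnan equilibrium
#'
#' \eqn{c^- = (-c_{FCD} + \sqrt{c_{FCD}^2 + 4 (\gamma_{ext}/\gamma_{int})^2
#' c_{ext}^2})/2}.
#'
#' @param c_FCD Fixed charge density (mol m^-3), >= 0.
#' @param params A \code{\link{material_params}} object.
#' @return Mobile anion concentration inside the tissue (mol m^-3).
#' @export
mobile_anion <- function(c_FCD, params) {
  stopifnot(all(c_FCD >= 0))
  g <- params$gamma_ext / params$gamma_int
  (-c_FCD + sqrt(c_FCD^2 + 4 * g^2 * params$c_ext^2)) / 2
}

#' Donnan osmotic swelling pressure
#'
#' \deqn{\Delta\pi = \phi_{int} R T \sqrt{c_{FCD}^2 +
#'   4 (\gamma_{ext}/\gamma_{int})^2 c_{ext}^2} - 2 \phi_{ext} R T c_{ext}}
#'
#' Vanishes at zero fixed charge density when internal and external osmotic
#' and activity coefficients are equal, and increases monotonically with
#' \code{c_FCD}.
#'
#' @param c_FCD Fixed charge density (mol m^-3), >= 0, vectorized.
#' @param params A \code{\link{material_params}} object.
#' @return Osmotic pressure difference (Pa).
#' @export
donnan_pressure <- function(c_FCD, params) {
  stopifnot(all(c_FCD >= 0))
  g <- params$gamma_ext / params$gamma_int
  RT <- params$R * params$T
  params$phi_int * RT * sqrt(c_FCD^2 + 4 * g^2 * params$c_ext^2) -
    2 * params$phi_ext * RT * params$c_ext
}

#' Chemical expansion stress
#'
#' Electrostatic repulsion of the proteoglycan fixed charges, screened by the
#' mobile ions:
#' \deqn{T_c = a_0 c_{FCD} \exp\big(-\kappa \frac{\gamma_{ext}}{\gamma_{int}}
#'   \sqrt{c^- (c^- + c_{FCD})}\big)}
#'
#' @param c_FCD Fixed charge density (mol m^-3), >= 0.
#' @param c_minus Mobile anion concentration (mol m^-3), >= 0; if missing it is
#'   computed with \code{\link{mobile_anion}}.
#' @param params A \code{\link{material_params}} object.
#' @return Chemical expansion stress (Pa), vectorized.
#' @export
chemical_expansion <- function(c_FCD, c_minus = NULL, params) {
  stopifnot(all(c_FCD >= 0))
  if (is.null(c_minus)) c_minus <- mobile_anion(c_FCD, params)
  stopifnot(all(c_minus >= 0))
  g <- params$gamma_ext / params$gamma_int
  params$a0 * c_FCD * exp(-params$kappa * g * sqrt(c_minus * (c_minus + c_FCD)))
}

#' Total Cauchy stress of the swollen tissue
#'
#' \deqn{\sigma_{tot} = \sigma_{nf} + \sum_k \sigma_f^k - T_c I - \Delta\pi I
#'   - p_{eff} I}
#' where \eqn{p_{eff}} is the effective fluid pressure: the water
#' chemical-potential contribution is folded together with the pore pressure
#' into a single pressure term, since only total boundary tractions are
#' observable.
#'
#' @param F Deformation gradient (3x3).
#' @param E_GL Green-Lagrange strain (3x3 symmetric).
#' @param directions Fibril direction set (see \code{\link{fibril_directions}}).
#' @param rho_z Collagen density fraction (-).
#' @param c_FCD0 Initial fixed charge density (mol m^-3).
#' @param n_fl0 Initial fluid fraction (-).
#' @param params A \code{\link{material_params}} object.
#' @param p Effective fluid pressure (Pa).
#' @param instantaneous Use the fast-rate fibril curve.
#' @return Symmetric 3x3 total Cauchy stress (Pa).
#' @export
total_stress <- function(F, E_GL, directions, rho_z, c_FCD0, n_fl0, params,
                         p = 0, instantaneous = FALSE) {
  J <- det(F)
  cf <- fcd_current(J, c_FCD0, n_fl0)
  Tc <- chemical_expansion(cf, params = params)
  dpi <- donnan_pressure(cf, params)
  neo_hookean_stress(F, params) +
    fibril_network_stress(E_GL, directions, rho_z, params, instantaneous) -
    (Tc + dpi + p) * diag(3)
}
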