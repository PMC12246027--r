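# Reaction-diffusion evolution of cells, enzyme stimulus, proteolytic
# enzymes, proteoglycans and NAC on the axisymmetric grid, plus the
# well-mixed analytic reduction used as a fast oracle.
#
# Operator splitting per step: implicit (backward-Euler) diffusion for the
# mobile species (NAC, enzyme), then reactions. Cell-fate and first-order
# reactions use exact exponential updates with NAC frozen over the step, so
# the damaged-pool split between death and recovery is exact at any dt;
# proteoglycan kinetics (slow, ~days) are stepped explicitly.

#' Construct the species state on a kinetics grid
#'
#' @param grid A \code{\link{kinetics_grid}}.
#' @param gamma_max Maximum shear strain per cell (vector of length
#'   \code{nr*nz}), or a \code{\link{strain_field}} to be sampled onto the
#'   grid by nearest sample point.
#' @param thresholds A \code{\link{damage_thresholds}}.
#' @param C_init Initial total cell density (cells m^-3).
#' @param profile A \code{\link{depth_profile}} used to initialize the
#'   proteoglycan field from the fixed charge density (\code{C_PG =
#'   c_FCD0(z)/2}: two fixed charges per disaccharide).
#' @return An object of class \code{species_state}.
#' @export
species_state <- function(grid, gamma_max,
                          thresholds = damage_thresholds(),
                          C_init = 0.5e14,
                          profile = make_depth_profile_fixture()) {
  if (inherits(gamma_max, "strain_field"))
    gamma_max <- sample_strain(gamma_max, grid$r, grid$z)
  stopifnot(length(gamma_max) == length(grid$r))
  cells <- seed_cell_field(gamma_max, thresholds, C_init)
  C_PG0 <- profile$fcd(grid$z / grid$thickness) / 2
  N <- length(grid$r)
  structure(list(grid = grid, time = 0,
                 C_h = cells$C_h, C_dmg = cells$C_dmg, C_dead = cells$C_dead,
                 C_init = C_init,
                 S = numeric(N), C_enz = numeric(N),
                 C_PG = C_PG0, C_PG_init = C_PG0,
                 C_NAC = numeric(N), n_clipped = 0L),
            class = "species_state")
}

#' @export
print.species_state <- function(x, ...) {
  cat(sprintf("Species state at t = %.3g h on %d x %d grid\n",
              x$time / 3600, x$grid$nr, x$grid$nz))
  cat(sprintf("  mean viability %.3f, mean rel. PG %.3f, mean NAC %.3g mM\n",
              mean((x$C_h + x$C_dmg) / x$C_init),
              mean(x$C_PG / x$C_PG_init), mean(x$C_NAC)))
  invisible(x)
}

# Death flux out of the damaged pool (damaged -> dead), cells m^-3 s^-1.
#' Damaged-cell death rate term
#'
#' First-order death flux \code{k_death * C_dmg} moving damaged cells to the
#' dead pool.
#'
#' @param C_dmg Damaged-cell concentration (cells m^-3), vectorized.
#' @param params A \code{\link{kinetics_params}}.
#' @return Death flux (cells m^-3 s^-1).
#' @export
cell_death_rhs <- function(C_dmg, params) params$k_death * C_dmg

#' NAC-mediated recovery rate term
#'
#' Second-order protection flux \code{k_rec * C_NAC * C_dmg} moving damaged
#' cells back to the healthy pool.
#'
#' @param C_dmg Damaged-cell concentration (cells m^-3).
#' @param C_NAC Local NAC concentration (mol m^-3).
#' @param params A \code{\link{kinetics_params}}.
#' @return Recovery flux (cells m^-3 s^-1).
#' @export
recovery_rhs <- function(C_dmg, C_NAC, params)
  params$k_rec * C_NAC * C_dmg

#' Enzyme-release stimulus rate term
#'
#' \code{dS/dt = alpha_aga * (k_aga * f_dmg - S)} where \code{f_dmg} is the
#' local damaged-cell fraction; the stimulus relaxes toward a level
#' proportional to the damaged population.
#'
#' @param S Stimulus (enzyme-release units).
#' @param C_dmg Damaged-cell concentration (cells m^-3).
#' @param C_init Total cell density used to form the damaged fraction.
#' @param params A \code{\link{kinetics_params}}.
#' @return dS/dt.
#' @export
stimulus_rhs <- function(S, C_dmg, C_init, params)
  params$alpha_aga * (params$k_aga * C_dmg / C_init - S)

#' Proteoglycan kinetics rate term
#'
#' Michaelis-Menten degradation by proteolytic enzymes plus a baseline
#' synthesis/turnover balance scaled by the viable-cell fraction:
#' \deqn{dC_{PG}/dt = -k_{cat} C_{enz} \frac{C_{PG}}{K_M + C_{PG}}
#'  - k_{turn} C_{PG} + k_{turn} C_{PG,init}\, viable}
#' Intact tissue (\code{C_enz = 0}, \code{viable = 1}, \code{C_PG =
#' C_PG_init}) is at steady state by construction.
#'
#' @param C_PG Proteoglycan concentration (mol m^-3), >= 0.
#' @param C_enz Enzyme concentration (enzyme units).
#' @param viable_fraction Viable (healthy + damaged) cell fraction in [0, 1].
#' @param C_PG_init Initial proteoglycan concentration (mol m^-3).
#' @param params A \code{\link{kinetics_params}}.
#' @return dC_PG/dt (mol m^-3 s^-1).
#' @export
pg_kinetics_rhs <- function(C_PG, C_enz, viable_fraction, C_PG_init, params) {
  stopifnot(all(C_PG >= 0))
  -params$k_cat * C_enz * C_PG / (params$K_M + C_PG) -
    params$k_turn * C_PG + params$k_turn * C_PG_init * viable_fraction
}

#' Enzyme rate term and diffusivity field
#'
#' Production equals the stimulus \code{S}; clearance is first order at
#' \code{k_enz_clear}. The effective enzyme diffusivity decreases with local
#' proteoglycan content: \code{D_enz = D_enz0 * exp(-a_enz * C_PG/C_PG_init)}
#' (a depleted matrix lets the large enzymes move more freely).
#'
#' @param C_enz Enzyme concentration.
#' @param S Stimulus field.
#' @param C_PG,C_PG_init Proteoglycan field and its initial value.
#' @param params A \code{\link{kinetics_params}}.
#' @return List with \code{rate} (dC_enz/dt, reaction part only) and
#'   \code{D_enz} (m^2 s^-1).
#' @export
enzyme_rhs <- function(C_enz, S, C_PG, C_PG_init, params) {
  list(rate = S - params$k_enz_clear * C_enz,
       D_enz = params$D_enz0 * exp(-params$a_enz * C_PG / C_PG_init))
}

# Build/refresh the operator cache used by the stepper.
.kin_cache <- function(state, params, dt, nac_bc) {
  grid <- state$grid
  nac_dir <- if (nac_bc == "dirichlet") c("top", "outer") else character(0)
  nac_fac <- if (params$D_NAC > 0)
    .fv_factor(grid, .fv_laplacian(grid, params$D_NAC, nac_dir), dt)
  enz <- enzyme_rhs(state$C_enz, state$S, state$C_PG, state$C_PG_init, params)
  enz_fac <- if (params$D_enz0 > 0)
    .fv_factor(grid, .fv_laplacian(grid, enz$D_enz), dt)
  list(nac = nac_fac, enz = enz_fac, dt = dt,
       pg_at_factor = state$C_PG)
}

# One operator-split step; cache must match dt. Returns updated state.
.kin_step_core <- function(state, params, c_bath, dt, cache) {
  # 1. implicit diffusion of mobile species
  if (!is.null(cache$nac))
    state$C_NAC <- .fv_solve(cache$nac, state$C_NAC, c_bath)
  if (!is.null(cache$enz))
    state$C_enz <- .fv_solve(cache$enz, state$C_enz, 0)
  # 2. cell fate: exact exponential update with NAC frozen over the step;
  #    the death/recovery split k_death : k_rec*C_NAC is exact at any dt
  kr <- params$k_rec * state$C_NAC
  ktot <- params$k_death + kr
  decay <- exp(-ktot * dt)
  dC <- state$C_dmg * (1 - decay)
  frac_dead <- ifelse(ktot > 0, params$k_death / pmax(ktot, 1e-300), 0)
  dmg_old <- state$C_dmg
  state$C_dead <- state$C_dead + dC * frac_dead
  state$C_h <- state$C_h + dC * (1 - frac_dead)
  state$C_dmg <- state$C_dmg * decay
  # 3. stimulus (exact relaxation toward k_aga * mean damaged fraction)
  f_dmg <- (dmg_old + state$C_dmg) / 2 / state$C_init
  ea <- exp(-params$alpha_aga * dt)
  S_old <- state$S
  state$S <- state$S * ea + params$k_aga * f_dmg * (1 - ea)
  # 4. enzyme reactions (production = stimulus, first-order clearance)
  S_bar <- (S_old + state$S) / 2
  if (params$k_enz_clear > 0) {
    ec <- exp(-params$k_enz_clear * dt)
    state$C_enz <- state$C_enz * ec +
      S_bar / params$k_enz_clear * (1 - ec)
  } else {
    state$C_enz <- state$C_enz + S_bar * dt
  }
  # 5. proteoglycan kinetics, explicit (rates are on the scale of days)
  viable <- (state$C_h + state$C_dmg) / state$C_init
  rate <- pg_kinetics_rhs(state$C_PG, state$C_enz, viable,
                          state$C_PG_init, params)
  pg_new <- state$C_PG + dt * rate
  neg <- pg_new < 0
  if (any(neg)) {
    lost <- -sum(state$grid$V[neg] * pg_new[neg])
    if (lost > 1e-3 * sum(state$grid$V * state$C_PG_init))
      stop("persistent negative proteoglycan mass during step; reduce dt")
    state$n_clipped <- state$n_clipped + sum(neg)
    pg_new[neg] <- 0
  }
  state$C_PG <- pg_new
  state$time <- state$time + dt
  state
}

#' Advance the reaction-diffusion system by one step
#'
#' Operator-split update: backward-Euler diffusion for NAC (Dirichlet bath
#' value on the top and outer surfaces per the schedule; zero flux on the
#' symmetry axis and bottom) and for proteolytic enzymes (zero flux on all
#' boundaries); then the reaction terms. Cells and proteoglycans do not
#' diffuse. Concentrations stay nonnegative; cell totals are conserved
#' nodewise by construction.
#'
#' For long runs prefer \code{\link{simulate_kinetics}}, which reuses the
#' operator factorizations across steps.
#'
#' @param state A \code{\link{species_state}}.
#' @param params A \code{\link{kinetics_params}}.
#' @param schedule A \code{\link{treatment_schedule}}.
#' @param dt Step size (s), positive.
#' @param nac_bc NAC boundary treatment: \code{"dirichlet"} (bath on free
#'   surfaces, the physical setting) or \code{"zeroflux"} (sealed; useful for
#'   conservation checks).
#' @return The updated \code{species_state}.
#' @export
step_reaction_diffusion <- function(state, params, schedule, dt,
                                    nac_bc = c("dirichlet", "zeroflux")) {
  stopifnot(inherits(state, "species_state"), dt > 0)
  nac_bc <- match.arg(nac_bc)
  cache <- .kin_cache(state, params, dt, nac_bc)
  c_bath <- bath_concentration_at(schedule, state$time + dt)
  .kin_step_core(state, params, c_bath, dt, cache)
}

#' Simulate the post-impact biology over time
#'
#' Runs the reaction-diffusion system from an initial strain-seeded state to
#' \code{t_end}, recording zone-averaged outputs at \code{record_times}.
#' Operator factorizations are cached; the enzyme diffusion operator (whose
#' diffusivity tracks the proteoglycan field) is refactorized whenever the
#' proteoglycan field has drifted by more than 2\% since the last
#' factorization.
#'
#' @param state A \code{\link{species_state}} (or a \code{\link{strain_field}}
#'   / strain vector, forwarded to \code{\link{species_state}} on the default
#'   grid).
#' @param params A \code{\link{kinetics_params}}.
#' @param schedule A \code{\link{treatment_schedule}}.
#' @param t_end End time (s).
#' @param dt Step size (s), default 60.
#' @param record_times Times at which to record outputs (s); always includes
#'   \code{t_end}.
#' @param zones List with elements \code{viability} (zone for viability
#'   reporting), \code{impacted} and \code{intact} (proteoglycan zones);
#'   defaults to \code{\link{standard_zones}}.
#' @param nac_bc See \code{\link{step_reaction_diffusion}}.
#' @return An object of class \code{kinetics_result}: list with \code{series}
#'   (data.frame: time_s, viability, relative_pg, mean_C_NAC, mean_C_enz) and
#'   \code{state} (final \code{species_state}).
#' @export
simulate_kinetics <- function(state, params = kinetics_params(),
                              schedule = treatment_schedule(bath_concentration = 0),
                              t_end, dt = 60,
                              record_times = NULL,
                              zones = NULL,
                              nac_bc = c("dirichlet", "zeroflux")) {
  nac_bc <- match.arg(nac_bc)
  if (!inherits(state, "species_state")) {
    grid <- kinetics_grid()
    state <- species_state(grid, state)
  }
  grid <- state$grid
  if (is.null(zones)) {
    sz <- standard_zones(grid$thickness)
    zones <- list(viability = sz$superficial_impacted,
                  impacted = sz$impacted_full, intact = sz$intact_full)
  }
  if (is.null(record_times)) record_times <- t_end
  record_times <- sort(unique(c(record_times, t_end)))
  stopifnot(t_end > 0, all(record_times > 0), all(record_times <= t_end))

  measure <- function(st) {
    viab <- zone_average((st$C_h + st$C_dmg) / st$C_init, grid$r, grid$z,
                         zones$viability, dr = grid$dr, dz = grid$dz)
    rpg <- relative_pg(st$C_PG, grid$r, grid$z, zones$impacted, zones$intact)
    data.frame(time_s = st$time, viability = viab, relative_pg = rpg,
               mean_C_NAC = mean(st$C_NAC), mean_C_enz = mean(st$C_enz))
  }

  cache <- .kin_cache(state, params, dt, nac_bc)
  out <- vector("list", length(record_times))
  k_rec_i <- 1L
  n_steps <- ceiling(t_end / dt - 1e-9)
  for (n in seq_len(n_steps)) {
    step_dt <- min(dt, t_end - state$time)
    if (step_dt <= 0) break
    if (abs(step_dt - cache$dt) > 1e-9 * dt ||
        max(abs(state$C_PG - cache$pg_at_factor) / state$C_PG_init) > 0.02)
      cache <- .kin_cache(state, params, step_dt, nac_bc)
    c_bath <- bath_concentration_at(schedule, state$time + step_dt)
    state <- .kin_step_core(state, params, c_bath, step_dt, cache)
    while (k_rec_i <= length(record_times) &&
           state$time >= record_times[k_rec_i] - 1e-6) {
      out[[k_rec_i]] <- measure(state)
      k_rec_i <- k_rec_i + 1L
    }
  }
  series <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  structure(list(series = series, state = state, params = params,
                 schedule = schedule, zones = zones),
            class = "kinetics_result")
}

#' @export
print.kinetics_result <- function(x, ...) {
  last <- x$series[nrow(x$series), ]
  cat(sprintf("Kinetics run to t = %.3g h (%d records)\n",
              last$time_s / 3600, nrow(x$series)))
  cat(sprintf("  final superficial viability %.1f%%, relative PG %.1f%%\n",
              100 * last$viability, 100 * last$relative_pg))
  invisible(x)
}

#' @export
summary.kinetics_result <- function(object, ...) {
  s <- object$series
  cat("Reaction-diffusion run summary\n")
  cat(sprintf("  horizon: %.3g h, %d records, schedule: delay %.1f h, bath %.1f mM for %.1f h\n",
              max(s$time_s) / 3600, nrow(s), object$schedule$delay / 3600,
              object$schedule$bath_concentration,
              object$schedule$duration / 3600))
  cat(sprintf("  superficial viability: start %.1f%%, end %.1f%%\n",
              100 * s$viability[1], 100 * utils::tail(s$viability, 1)))
  cat(sprintf("  relative PG: end %.1f%% (deficit %.1f points)\n",
              100 * utils::tail(s$relative_pg, 1),
              100 * (1 - utils::tail(s$relative_pg, 1))))
  invisible(object)
}

#' @export
plot.kinetics_result <- function(x, ...) {
  s <- x$series
  graphics::par(mfrow = c(1, 2))
  graphics::plot(s$time_s / 3600, 100 * s$viability, type = "l",
                 xlab = "time (h)", ylab = "viability (%)", ylim = c(0, 100), ...)
  graphics::plot(s$time_s / 86400, 100 * s$relative_pg, type = "l",
                 xlab = "time (d)", ylab = "relative PG (%)", ...)
  graphics::par(mfrow = c(1, 1))
  invisible(x)
}

#' Well-mixed analytic viability (closed form)
#'
#' Analytic reduction of the cell-fate kinetics when NAC is at the bath
#' concentration everywhere: before the treatment delay the damaged pool
#' decays at \code{k_death} (all losses die); afterwards it decays at
#' \code{k_death + k_rec*c_nac} with fraction
#' \code{k_rec*c_nac/(k_death + k_rec*c_nac)} recovering to healthy.
#' Viability is one minus the dead fraction.
#'
#' @param damage0 Initial damaged fraction in [0, 1].
#' @param k_death Death rate (s^-1).
#' @param k_rec Protection rate (m^3 mol^-1 s^-1).
#' @param c_nac NAC concentration during treatment (mol m^-3).
#' @param delay Treatment delay (s).
#' @param t_eval Evaluation time(s) (s), vectorized.
#' @return Viability fraction(s) in [0, 1].
#' @export
wellmixed_viability <- function(damage0, k_death, k_rec = 0, c_nac = 0,
                                delay = 0, t_eval) {
  stopifnot(damage0 >= 0, damage0 <= 1, k_death >= 0, k_rec >= 0,
            c_nac >= 0, delay >= 0, all(t_eval >= 0))
  ktot <- k_death + k_rec * c_nac
  fdead <- if (ktot > 0) k_death / ktot else 0
  vapply(t_eval, function(t) {
    if (t <= delay || k_rec * c_nac == 0)
      return(1 - damage0 * (1 - exp(-k_death * t)))
    d1 <- damage0 * exp(-k_death * delay)   # damaged pool at bath onset
    dead1 <- damage0 - d1                   # death-only losses before onset
    d2 <- d1 * exp(-ktot * (t - delay))
    1 - (dead1 + (d1 - d2) * fdead)
  }, numeric(1))
}

#' Damaged-cell exposure integral
#'
#' \eqn{\int_0^{horizon} C_{dmg}(t)/C_{init}\, dt} under the well-mixed
#' kinetics: the total damaged-cell exposure that drives enzyme release.
#' Because the stimulus equation is linear, total enzyme production scales
#' with this integral, so predicted proteoglycan-deficit ratios across
#' treatment arms approximate ratios of these integrals.
#'
#' @inheritParams wellmixed_viability
#' @param horizon Upper limit of the integral (s), default Inf.
#' @return Exposure integral (s).
#' @export
exposure_integral <- function(damage0, k_death, k_rec = 0, c_nac = 0,
                              delay = 0, horizon = Inf) {
  stopifnot(k_death > 0)
  ktot <- k_death + k_rec * c_nac
  if (k_rec * c_nac == 0 || is.infinite(delay)) {
    if (is.infinite(horizon)) return(damage0 / k_death)
    return(damage0 * (1 - exp(-k_death * horizon)) / k_death)
  }
  d1 <- damage0 * exp(-k_death * min(delay, horizon))
  part1 <- (damage0 - d1) / k_death
  if (horizon <= delay) return(part1)
  d2 <- d1 * exp(-ktot * (horizon - delay))
  part1 + (d1 - d2) / ktot
}
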