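# Reaction-diffusion kinetics: conservation, limits, analytic reductions.

test_that("a fully healthy, untreated tissue does not evolve", {
  g <- kinetics_grid(10, 6)
  st <- species_state(g, rep(0, length(g$r)))
  res <- simulate_kinetics(st, kinetics_params(k_aga = 1),
                           treatment_schedule(bath_concentration = 0),
                           t_end = 6 * HOUR, dt = 600)
  s <- res$state
  expect_equal(s$C_h, st$C_h)
  expect_equal(max(abs(s$C_PG - s$C_PG_init)) / max(s$C_PG_init), 0,
               tolerance = 1e-12)
  expect_equal(max(s$C_enz), 0)
  expect_equal(res$series$viability, 1)
})

test_that("cells are conserved nodewise through a treated run", {
  g <- kinetics_grid(12, 8)
  st <- species_state(g, ref_field())
  res <- simulate_kinetics(st, kinetics_params(k_aga = 1e-4),
                           treatment_schedule(delay = HOUR, duration = 86400),
                           t_end = 12 * HOUR, dt = 300)
  s <- res$state
  expect_lt(max(abs((s$C_h + s$C_dmg + s$C_dead) / s$C_init - 1)), 1e-10)
  for (f in list(s$C_h, s$C_dmg, s$C_dead, s$S, s$C_enz, s$C_PG, s$C_NAC))
    expect_true(all(f >= 0))
})

test_that("NAC mass is conserved with sealed boundaries and no reactions", {
  g <- kinetics_grid(12, 8)
  st <- species_state(g, rep(0, length(g$r)))
  st$C_NAC <- 1 + g$r / max(g$r) + g$z / max(g$z)   # arbitrary smooth field
  p <- kinetics_params(k_rec = 0)                   # no NAC-consuming reaction
  m0 <- sum(g$V * st$C_NAC)
  res <- simulate_kinetics(st, p, treatment_schedule(bath_concentration = 0),
                           t_end = 2 * HOUR, dt = 60, nac_bc = "zeroflux")
  m1 <- sum(g$V * res$state$C_NAC)
  expect_lt(abs(m1 - m0) / m0, 1e-10)
})

test_that("well-mixed PDE limit matches the analytic cell-fate solution", {
  g <- kinetics_grid(10, 6)
  st <- species_state(g, ref_field())
  whole <- zone_spec(0, 12.5e-3, 0, 1e-3, "whole tissue")
  d0 <- zone_average(st$C_dmg / st$C_init, g$r, g$z, whole, dr = g$dr, dz = g$dz)
  p <- kinetics_params(D_NAC = 1e-4)   # near-instant equilibration to the bath
  res <- simulate_kinetics(st, p, treatment_schedule(delay = 0, duration = 3 * 86400),
                           t_end = 24 * HOUR, dt = 60,
                           zones = list(viability = zone_spec(0, 12.5e-3, 0, 1e-3),
                                        impacted = zone_spec(0, 2e-3, 0, 1e-3),
                                        intact = zone_spec(8e-3, 10e-3, 0, 1e-3)))
  v_pde <- utils::tail(res$series$viability, 1)
  v_ode <- wellmixed_viability(d0, p$k_death, p$k_rec, 2, 0, 24 * HOUR)
  expect_lt(abs(v_pde - v_ode), 0.001)   # 0.1 percentage point
})

test_that("stimulus kinetics: steady state, decay, and integral identity", {
  p <- kinetics_params(k_aga = 2, alpha_aga = 1e-4)
  # steady state: dS/dt = 0 at S = k_aga * damaged fraction
  expect_equal(stimulus_rhs(2 * 0.3, 0.3 * 1e14, 1e14, p), 0)
  # pure decay when no damage
  expect_equal(stimulus_rhs(1, 0, 1e14, p), -p$alpha_aga)
  # integral identity: int S dt = k_aga * int f_dmg dt for S(0) = 0
  g <- kinetics_grid(4, 3)
  st <- species_state(g, rep(2.0, length(g$r)))   # fully damaged
  dt <- 60; n <- 4000
  S_int <- 0; f_int <- 0
  pk <- kinetics_params(k_aga = 2, alpha_aga = 1e-4, k_death = 6.9e-5,
                        D_NAC = 0, D_enz0 = 0)
  sched <- treatment_schedule(bath_concentration = 0)
  for (i in seq_len(n)) {
    f_prev <- st$C_dmg[1] / st$C_init
    st <- step_reaction_diffusion(st, pk, sched, dt)
    S_int <- S_int + st$S[1] * dt
    f_int <- f_int + (f_prev + st$C_dmg[1] / st$C_init) / 2 * dt
  }
  # at the horizon both integrals are nearly complete (t >> 1/k_death, 1/alpha)
  expect_equal(S_int, pk$k_aga * f_int, tolerance = 0.02)
})

test_that("enzyme kinetics: decay, PG-dependent diffusivity, mass balance", {
  p <- kinetics_params()
  out <- enzyme_rhs(2, 0, 50, 100, p)
  expect_equal(out$rate, -p$k_enz_clear * 2)
  # depleted matrix -> faster enzyme transport
  D_low_pg <- enzyme_rhs(0, 0, 20, 100, p)$D_enz
  D_high_pg <- enzyme_rhs(0, 0, 100, 100, p)$D_enz
  expect_gt(D_low_pg, D_high_pg)
  # production-minus-clearance mass balance with sealed boundaries:
  # constant stimulus (alpha = 0 keeps S frozen), no clearance
  g <- kinetics_grid(8, 5)
  st <- species_state(g, rep(0, length(g$r)))
  st$S <- rep(1e-6, length(g$r))
  pk <- kinetics_params(alpha_aga = 0, k_enz_clear = 0, k_aga = 0)
  m0 <- sum(g$V * st$C_enz)
  tend <- 2 * HOUR
  res <- simulate_kinetics(st, pk, treatment_schedule(bath_concentration = 0),
                           t_end = tend, dt = 60)
  m1 <- sum(g$V * res$state$C_enz)
  expect_equal(m1 - m0, sum(g$V * 1e-6) * tend, tolerance = 1e-8)
})

test_that("proteoglycan kinetics: intact steady state and Michaelis-Menten limits", {
  p <- kinetics_params()
  # intact tissue: no enzyme, full viability, PG at its initial value
  expect_equal(pg_kinetics_rhs(120, 0, 1, 120, p), 0)
  # zeroth-order regime at PG >> K_M
  r1 <- -pg_kinetics_rhs(1e6, 2, 1, 1e6, kinetics_params(k_turn = 0))
  expect_equal(r1, p$k_cat * 2, tolerance = 1e-3)
  # first-order regime at PG << K_M
  r2 <- -pg_kinetics_rhs(1e-3, 2, 1, 1e-3, kinetics_params(k_turn = 0))
  expect_equal(r2, p$k_cat * 2 * 1e-3 / p$K_M, tolerance = 1e-3)
})

test_that("NAC penetration: superficial zone equilibrates within ~10 minutes", {
  # diffusion-time sanity: L^2/D = (200 um)^2 / 1.2e-10 ~ 5.6 min
  g <- kinetics_grid(20, 20)
  st <- species_state(g, rep(0, length(g$r)))
  res <- simulate_kinetics(st, kinetics_params(),
                           treatment_schedule(delay = 0, duration = HOUR),
                           t_end = 10 * 60, dt = 30)
  sup <- standard_zones()$superficial_impacted
  nac_sup <- zone_average(res$state$C_NAC, g$r, g$z, sup, dr = g$dr, dz = g$dz)
  expect_gt(nac_sup, 0.75 * 2)
})

test_that("well-mixed closed form: known values and pure-death consistency", {
  # no treatment reduces to the pure-death exponential
  expect_equal(wellmixed_viability(0.56, 6.9e-5, 0, 0, 0, 14400),
               0.44 + 0.56 * exp(-6.9e-5 * 14400))
  expect_equal(wellmixed_viability(0.56, 6.9e-5, 0.53e-4, 0, 0, 14400),
               wellmixed_viability(0.56, 6.9e-5, 0, 0, 0, 14400))
  # asymptotic recovered fraction under constant NAC = k_rec*C/(k_death+k_rec*C)
  v_inf <- wellmixed_viability(0.56, 6.9e-5, 0.53e-4, 2, 0, 60 * 86400)
  expect_equal(v_inf, 0.44 + 0.56 * (1.06 / 1.75), tolerance = 1e-6)
  # viability nonincreasing in delay
  v <- wellmixed_viability(0.56, 6.9e-5, 0.53e-4, 2,
                           delay = 0, t_eval = 48 * HOUR)
  for (d in c(1, 2, 4, 8, 12) * HOUR) {
    v_d <- wellmixed_viability(0.56, 6.9e-5, 0.53e-4, 2, d, 48 * HOUR)
    expect_lte(v_d, v + 1e-12)
    v <- v_d
  }
})

test_that("exposure integral: closed form against numerical quadrature", {
  d0 <- 0.56; kd <- 6.9e-5; kr <- 0.53e-4; c <- 2; delay <- 4 * HOUR
  tt <- seq(0, 3e6, by = 10)
  dmg <- ifelse(tt <= delay, d0 * exp(-kd * tt),
                d0 * exp(-kd * delay) * exp(-(kd + kr * c) * (tt - delay)))
  quad <- sum((dmg[-1] + dmg[-length(dmg)]) / 2) * 10   # trapezoid rule
  expect_equal(exposure_integral(d0, kd, kr, c, delay), quad, tolerance = 1e-4)
  expect_equal(exposure_integral(d0, kd), d0 / kd)
})
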