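# Material-point verification of the constitutive model.

test_that("Neo-Hookean stress vanishes in reference and under pure rotation", {
  mp <- ref_material()
  expect_equal(neo_hookean_stress(diag(3), mp), matrix(0, 3, 3))
  set.seed(11)
  for (i in 1:5) {
    R <- random_rotation()
    expect_lt(max(abs(neo_hookean_stress(R, mp))), 1e-8 * mp$E_nf)
  }
  expect_error(neo_hookean_stress(diag(c(-1, 1, 1)), mp), "positive")
})

test_that("Neo-Hookean stress matches the numerical energy derivative", {
  mp <- ref_material(E_nf = 1e6, nu_nf = 0.1)
  set.seed(7)
  Fs <- c(list(diag(c(1.1, 1, 1))),
          lapply(1:4, function(i) diag(3) + matrix(stats::runif(9, -0.05, 0.05), 3, 3)))
  h <- 1e-6
  for (F in Fs) {
    sig <- neo_hookean_stress(F, mp)
    P <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      Fp <- F; Fp[i, j] <- Fp[i, j] + h
      Fm <- F; Fm[i, j] <- Fm[i, j] - h
      P[i, j] <- (neo_hookean_energy(Fp, mp) - neo_hookean_energy(Fm, mp)) / (2 * h)
    }
    sig_num <- P %*% t(F) / det(F)
    expect_lt(max(abs(sig - sig_num)) / max(abs(sig)), 1e-6)
  }
})

test_that("Neo-Hookean stress is objective", {
  mp <- ref_material()
  set.seed(21)
  for (i in 1:5) {
    F <- diag(3) + matrix(stats::runif(9, -0.1, 0.1), 3, 3)
    R <- random_rotation()
    s1 <- neo_hookean_stress(R %*% F, mp)
    s2 <- R %*% neo_hookean_stress(F, mp) %*% t(R)
    expect_lt(max(abs(s1 - s2)), 1e-8 * max(abs(s2), 1))
  }
})

test_that("fibril stress is tension-only and reduces to E0*eps when eta = 0", {
  mp <- ref_material(E0 = 10e6, E_eps = 50e6, eta = 1e5)
  st <- fibril_stress_update(-0.05, fibril_history(), mp, dt = 0.1)
  expect_identical(st$sigma_f, 0)
  mp0 <- ref_material(E0 = 10e6, E_eps = 50e6, eta = 0)
  st0 <- fibril_stress_update(0.02, fibril_history(), mp0, dt = 0.1)
  expect_equal(st0$sigma_f, 0.2e6)
})

test_that("fibril rate limits: slow ramp relaxes to E0*eps, fast ramp reaches the
           instantaneous curve E0*eps + E_eps*eps^2", {
  mp <- ref_material(E0 = 10e6, E_eps = 50e6, eta = 1e5)
  eps <- 0.05
  slow <- fibril_ramp(eps, rate = 1e-6, mp)
  expect_lt(abs(slow - mp$E0 * eps) / (mp$E0 * eps), 0.01)
  fast <- fibril_ramp(eps, rate = 1e3, mp)
  inst <- mp$E0 * eps + mp$E_eps * eps^2
  expect_lt(abs(fast - inst) / inst, 0.01)
})

test_that("implicit fibril update matches an independent ODE integration", {
  skip_if_not_installed("deSolve")
  mp <- ref_material(E0 = 10e6, E_eps = 50e6, eta = 1e5)
  rate <- 1  # 1/s ramp, intermediate regime where the dashpot partly flows
  eps_end <- 0.05
  # overstress ODE: du/dt = (2 sqrt(Ee u)/eta) (eta*rate - u)
  f <- function(t, u, p) {
    list((2 * sqrt(pmax(mp$E_eps * u, 1e-20)) / mp$eta) * (mp$eta * rate - u))
  }
  sol <- deSolve::ode(y = c(u = 1e-12), times = seq(0, eps_end / rate, length.out = 200),
                      func = f, parms = NULL, rtol = 1e-10, atol = 1e-14)
  u_ref <- sol[nrow(sol), "u"]
  sig_ref <- mp$E0 * eps_end + u_ref
  sig <- fibril_ramp(eps_end, rate, mp, n = 2000)
  expect_lt(abs(sig - sig_ref) / sig_ref, 0.005)
})

test_that("fibril network stress respects tension-only and geometry", {
  mp <- ref_material(E0 = 10e6)
  prof <- ref_profile()
  dirs <- fibril_directions(0.5, prof)
  # all-compressive strain -> zero tensor
  sig <- fibril_network_stress(diag(c(-0.1, -0.1, -0.1)), dirs, 0.2, mp)
  expect_equal(sig, matrix(0, 3, 3))
  # single primary fibril along z with known stress
  dirs_z <- list(primary = matrix(c(0, 0, 1), 1, 3), secondary = NULL)
  E <- diag(c(0, 0, 0.1))
  sig_z <- fibril_network_stress(E, dirs_z, 0.5, mp, instantaneous = FALSE)
  expect_equal(sig_z[3, 3], 0.5 * mp$C * mp$E0 * 0.1)
  expect_equal(sig_z[1, 1], 0)
  # isotropic secondary set under equibiaxial stretch: in-plane isotropy
  dirs_s <- list(primary = NULL, secondary = dirs$secondary)
  Eb <- diag(c(0.05, 0.05, -0.02))
  sig_b <- fibril_network_stress(Eb, dirs_s, 0.2, mp)
  expect_equal(sig_b, t(sig_b))
  expect_equal(sig_b[1, 1], sig_b[2, 2], tolerance = 1e-12)
})

test_that("permeability follows k0 * J^M", {
  mp <- ref_material(k0 = 1e-15, M = 5)
  expect_equal(permeability(1, mp), 1e-15)
  expect_equal(permeability(0.8, mp), 3.2768e-16)
  mp0 <- ref_material(k0 = 1e-15, M = 0)
  expect_equal(permeability(c(0.5, 1, 2), mp0), rep(1e-15, 3))
  expect_error(permeability(-0.1, mp), "positive")
})

test_that("current fixed charge density conserves fixed charges exactly", {
  expect_equal(fcd_current(1, 200, 0.8), 200)
  expect_equal(fcd_current(0.9, 200, 0.8), 200 * 0.8 / 0.7)
  # compression concentrates charges monotonically
  J <- seq(0.5, 1.2, by = 0.05)
  cf <- fcd_current(J, 200, 0.8)
  expect_true(all(diff(cf) < 0))
  # conservation identity c_FCD * (n_fl0 - 1 + J) = c_FCD0 * n_fl0
  expect_equal(cf * (0.8 - 1 + J), rep(200 * 0.8, length(J)))
  expect_error(fcd_current(0.1, 200, 0.8), "collapse")
})

test_that("Donnan pressure: zero at zero FCD with equal coefficients, closed form,
           monotone", {
  mp <- ref_material(gamma_ext = 1, gamma_int = 1, phi_ext = 1, phi_int = 1,
                     T = 310, c_ext = 150)
  expect_equal(donnan_pressure(0, mp), 0)
  expect_lt(abs(donnan_pressure(1e-9, mp)), 1e-3)  # continuity at 0
  expect_equal(donnan_pressure(200, mp),
               8.3145 * 310 * (sqrt(200^2 + 4 * 150^2) - 300))
  cf <- seq(0, 400, by = 20)
  expect_true(all(diff(donnan_pressure(cf, mp)) > 0))
  expect_true(all(donnan_pressure(cf, mp) >= 0))
})

test_that("chemical expansion stress behaves per its closed form", {
  mp <- ref_material()
  expect_equal(chemical_expansion(0, params = mp), 0)
  mp0 <- ref_material(kappa = 0)
  expect_equal(chemical_expansion(200, 150, mp0), mp0$a0 * 200)
  # screening: decreasing in mobile anion concentration
  tc <- vapply(c(50, 150, 300), function(cm)
    chemical_expansion(200, cm, mp), numeric(1))
  expect_true(all(diff(tc) < 0))
})

test_that("total stress reduces to zero in the reference state and to -dpi*I for
           pure osmotic loading", {
  mp <- ref_material(gamma_ext = 1, gamma_int = 1, phi_ext = 1, phi_int = 1)
  prof <- ref_profile()
  dirs <- fibril_directions(0.5, prof)
  # reference configuration, no charge, no pressure
  sig <- total_stress(diag(3), matrix(0, 3, 3), dirs, 0.2,
                      c_FCD0 = 0, n_fl0 = 0.8, params = mp, p = 0)
  expect_equal(sig, matrix(0, 3, 3))
  # only Donnan pressure active
  mp2 <- ref_material(a0 = 0)  # switch off chemical expansion
  sig2 <- total_stress(diag(3), matrix(0, 3, 3), dirs, 0.2,
                       c_FCD0 = 200, n_fl0 = 0.8, params = mp2, p = 0)
  dpi <- donnan_pressure(200, mp2)
  expect_equal(sig2, -dpi * diag(3))
})

test_that("mobile anion concentration satisfies the Donnan equilibrium relation", {
  mp <- ref_material()
  cf <- c(0, 50, 200, 400)
  cm <- mobile_anion(cf, mp)
  g <- mp$gamma_ext / mp$gamma_int
  # c-(c- + cFCD) = (g c_ext)^2
  expect_equal(cm * (cm + cf), rep((g * mp$c_ext)^2, length(cf)))
})
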