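# Impact stage: waveform, strain extraction, field exchange, swelling and a
# small transient solve. The heavier convergence/force-sweep checks live in
# the acceptance suite.

test_that("half-sine waveform peaks at mid-impact and averages 2/pi of the peak", {
  ld <- load_spec(F_peak = 4000, t_impact = 1e-3)
  expect_equal(force_waveform(0.5e-3, ld), 4000)
  expect_equal(force_waveform(0, ld), 0)
  expect_equal(force_waveform(1e-3, ld), 0, tolerance = 1e-9)
  tt <- seq(0, 1e-3, length.out = 20001)
  expect_equal(mean(force_waveform(tt, ld)), 2 / pi * 4000, tolerance = 1e-4)
  expect_warning(force_waveform(2e-3, ld), "outside")
})

test_that("maximum shear strain from the Green-Lagrange tensor", {
  expect_equal(max_shear_strain(matrix(0, 3, 3)), 0)
  expect_equal(max_shear_strain(diag(c(0.3, 0, -0.1))), 0.2)
  expect_equal(max_shear_strain(diag(c(0.3, 0, -0.1)), halved = FALSE), 0.4)
  expect_error(max_shear_strain(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3, 3)),
               "symmetric")
  # rotation invariance against a fresh eigen decomposition
  set.seed(5)
  for (i in 1:10) {
    E <- random_sym3()
    R <- random_rotation()
    g1 <- max_shear_strain(E)
    g2 <- max_shear_strain(R %*% E %*% t(R))
    ev <- eigen(E, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(g1, (max(ev) - min(ev)) / 2, tolerance = 1e-12)
    expect_equal(g1, g2, tolerance = 1e-9)
  }
})

test_that("strain-field CSV round trip is lossless and schema-checked", {
  f <- ref_field()
  path <- tempfile(fileext = ".csv")
  export_strain_field(f, path)
  f2 <- load_strain_field(path)
  expect_equal(as.data.frame(f2), as.data.frame(f), tolerance = 1e-14)
  expect_equal(attr(f2, "time"), attr(f, "time"))
  # missing column -> schema error naming it
  df <- utils::read.csv(path, comment.char = "#")
  df$gamma_max <- NULL
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE)
  expect_error(load_strain_field(path2), "gamma_max")
  expect_error(load_strain_field(tempfile()), "no such file")
})

test_that("swelling pre-state: no charge means no displacement, swelling lifts the
           surface, and higher bath salinity reduces it", {
  # equal internal/external coefficients so zero fixed charge means exactly
  # zero osmotic driver
  mp <- ref_material(gamma_ext = 0.9, gamma_int = 0.9,
                     phi_ext = 0.9, phi_int = 0.9)
  ms <- mesh_spec(12, 5)
  zf <- depth_profile(c(0, 1), c(0, 0), c(0.8, 0.8), c(0.2, 0.2))
  sw0 <- initial_swelling_solve(ms, zf, mp)
  expect_equal(max(abs(sw0$u)), 0)
  prof <- depth_profile(c(0, 1), c(200, 200), c(0.8, 0.8), c(0.2, 0.2))
  sw1 <- initial_swelling_solve(ms, prof, mp)
  expect_gt(sw1$surface_uplift, 0)
  mp2 <- ref_material(c_ext = 300)
  sw2 <- initial_swelling_solve(ms, prof, mp2)
  expect_lt(sw2$surface_uplift, sw1$surface_uplift)
})

test_that("zero peak force produces a null strain field", {
  fld <- impact_solve(mesh_spec(12, 5), load_spec(F_peak = 0),
                      params = ref_material(), profile = ref_profile(),
                      n_steps = 10, n_picard = 1)
  expect_lt(max(fld$gamma_max), 1e-12)
  expect_lt(max(abs(fld$pore_pressure_Pa)), 1e-6)
})

test_that("a small transient impact solve honours the load path and concentrates
           strain under the indenter", {
  fld <- impact_solve(mesh_spec(20, 10), load_spec(), params = ref_material(),
                      profile = ref_profile(), n_steps = 20, n_picard = 2)
  d <- attr(fld, "diagnostics")
  # quasi-static equilibrium: bottom reaction tracks the applied waveform
  ipk <- which.max(d$applied)
  expect_lt(abs(d$reaction[ipk] - d$applied[ipk]) / d$applied[ipk], 0.05)
  # strain localized under the contact
  expect_gt(mean(fld$gamma_max[fld$r_m <= 2.5e-3]),
            5 * mean(fld$gamma_max[fld$r_m >= 5e-3]))
  # near-undrained over 1 ms
  expect_lt(d$fluid_loss_fraction, 0.01)
  expect_true(all(fld$gamma_max >= 0))
})
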