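# Synthetic strain fields and depth profiles.

test_that("reference strain preset encodes 56% superficial damage", {
  f <- make_strain_fixture()
  zone <- standard_zones()$superficial_impacted
  dmg <- zone_average(damage_fraction(f$gamma_max), f$r_m, f$z_m, zone)
  expect_equal(dmg, 0.56, tolerance = 0.005)
  # plateau under the indenter, Gaussian decay beyond
  expect_equal(max(f$gamma_max), 0.679, tolerance = 1e-9)
  expect_true(all(f$gamma_max[f$r_m > 2.5e-3] < 0.679))
  expect_lt(mean(f$gamma_max[f$r_m > 10e-3]), 1e-3)
})

test_that("uniform zero-peak fixture is identically zero", {
  f <- make_strain_fixture(fixture_spec(pattern = "uniform", peak = 0))
  expect_true(all(f$gamma_max == 0))
})

test_that("fixtures are deterministic: same seed gives byte-identical files", {
  sp <- fixture_spec(noise_sd = 0.05, seed = 42)
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  make_strain_fixture(sp, p1)
  make_strain_fixture(sp, p2)
  expect_identical(readLines(p1), readLines(p2))
  # and the file passes the loader's schema validation
  f <- load_strain_field(p1)
  expect_s3_class(f, "strain_field")
  # a different seed changes the field
  p3 <- tempfile(fileext = ".csv")
  make_strain_fixture(fixture_spec(noise_sd = 0.05, seed = 43), p3)
  expect_false(identical(readLines(p1), readLines(p3)))
})

test_that("synthetic depth profile is physiological and monotone", {
  prof <- make_depth_profile_fixture()
  z <- seq(0, 1, by = 0.05)
  expect_true(all(prof$nfl(z) > 0.6 & prof$nfl(z) < 0.9))
  expect_true(all(diff(prof$fcd(z)) >= 0))
  expect_true(all(diff(prof$nfl(z)) <= 0))
  # arcade: surface-parallel at the top, depth-aligned at the bottom
  expect_equal(prof$angle(0), pi / 2)
  expect_equal(prof$angle(1), 0)
  d <- fibril_directions(0, prof)
  expect_equal(rowSums(d$primary^2), c(1, 1))
  expect_equal(unname(rowSums(d$secondary^2)), rep(1, 13))
})

test_that("depth profile round-trips through config serialization", {
  prof <- make_depth_profile_fixture()
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(zhat = prof$zhat, c_FCD0 = prof$c_FCD0,
                        n_fl0 = prof$n_fl0, rho_z = prof$rho_z), path)
  raw <- yaml::read_yaml(path)
  prof2 <- depth_profile(raw$zhat, raw$c_FCD0, raw$n_fl0, raw$rho_z)
  z <- seq(0, 1, by = 0.01)
  expect_equal(prof2$fcd(z), prof$fcd(z), tolerance = 1e-6)
  expect_equal(prof2$nfl(z), prof$nfl(z), tolerance = 1e-6)
})
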