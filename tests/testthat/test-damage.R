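# Strain-thresholded cell damage and zone averaging.

test_that("damage function branches, continuity and known values", {
  th <- damage_thresholds(0.40, 1.50)
  expect_equal(damage_fraction(0.30, th), 0)
  expect_equal(damage_fraction(1.60, th), 1)
  expect_equal(damage_fraction(1.50, th), 1)       # branch continuity at eps_max
  expect_equal(damage_fraction(0.40, th), 0)       # and at eps_init
  expect_equal(damage_fraction(0.679, th),
               (1.5 / 0.679) * (0.679 - 0.40) / 1.10)
  expect_equal(damage_fraction(0.679, th), 0.56, tolerance = 1e-3)
  # continuity at both thresholds to 1e-9 perturbation
  eps <- 1e-9
  expect_lt(abs(damage_fraction(0.40 + eps, th) - damage_fraction(0.40 - eps, th)), 1e-7)
  expect_lt(abs(damage_fraction(1.50 + eps, th) - damage_fraction(1.50 - eps, th)), 1e-7)
})

test_that("damage function is nondecreasing in strain and nonincreasing in eps_max", {
  th <- damage_thresholds()
  g <- seq(0, 2.5, by = 0.01)
  expect_true(all(diff(damage_fraction(g, th)) >= -1e-12))
  # sensitivity ordering behind the 65% / 56% / 52% sequence
  f <- vapply(c(1.0, 1.5, 2.0), function(em)
    damage_fraction(0.679, damage_thresholds(0.40, em)), numeric(1))
  expect_true(all(diff(f) < 0))
  expect_gte(f[1], 0.60); expect_lte(f[1], 0.70)
  expect_gte(f[3], 0.48); expect_lte(f[3], 0.55)
})

test_that("damage_inverse inverts the rising branch", {
  th <- damage_thresholds()
  for (f in c(0, 0.2, 0.56, 0.9))
    expect_equal(damage_fraction(damage_inverse(f, th), th), f, tolerance = 1e-12)
  expect_equal(damage_inverse(0.56, th), 0.679, tolerance = 2e-3)
})

test_that("seeding the cell field conserves cells nodewise", {
  th <- damage_thresholds()
  g <- c(0, 0.3, 0.679, 2.0)
  cf <- seed_cell_field(g, th, C_init = 0.5e14)
  expect_equal(cf$C_h + cf$C_dmg + cf$C_dead, rep(0.5e14, 4))
  expect_equal(cf$C_dmg[1], 0)                      # no strain, all healthy
  expect_equal(cf$C_dmg[4], 0.5e14)                 # above eps_max, all damaged
  expect_true(all(cf$C_dead == 0))
  expect_error(seed_cell_field(c(-0.1, 0.2), th), "negative")
})

test_that("zone average is the exact axisymmetric volume-weighted mean", {
  # uniform field returns the value itself
  g <- kinetics_grid(10, 5, radius = 10e-3, thickness = 1e-3)
  zone <- zone_spec(0, 10e-3, 0, 1e-3)
  expect_equal(zone_average(rep(3.7, length(g$r)), g$r, g$z, zone,
                            dr = g$dr, dz = g$dz), 3.7)
  # two-cell hand computation: cells at r = 0.5 and 1.5 (dr = 1, dz = 1)
  vals <- c(2, 10)
  r <- c(0.5, 1.5); z <- c(0.5, 0.5)
  w <- pi * c(1^2 - 0^2, 2^2 - 1^2)   # annulus areas * dz
  hand <- sum(w * vals) / sum(w)
  expect_equal(zone_average(vals, r, z, zone_spec(0, 2, 0, 1), dr = 1, dz = 1),
               hand)
  expect_error(zone_average(vals, r, z, zone_spec(5, 6, 0, 1), dr = 1, dz = 1),
               "empty zone")
})

test_that("relative PG is a ratio of zone means with guarded denominator", {
  g <- kinetics_grid(20, 4)
  zones <- standard_zones()
  pg <- rep(100, length(g$r))
  pg[g$r <= 2e-3] <- 85
  expect_equal(relative_pg(pg, g$r, g$z, zones$impacted_full, zones$intact_full),
               0.85)
  expect_equal(relative_pg(pg, g$r, g$z, zones$intact_full, zones$intact_full), 1)
  expect_error(relative_pg(0 * pg, g$r, g$z, zones$impacted_full,
                           zones$intact_full), "zero")
})
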