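# Scenario orchestration: consistency, monotonicity, calibration mechanics.

test_that("untreated time course declines and k_rec = 0 equals untreated", {
  tc <- run_untreated_timecourse()
  expect_true(all(diff(tc$viability) < 0))
  ps <- run_protection_sweep(k_recs = c(0, 0.53e-4))
  un <- run_untreated_timecourse(times = 48 * HOUR)
  expect_equal(ps$viability[1], un$viability, tolerance = 1e-12)
  expect_gt(ps$viability[2], ps$viability[1])
})

test_that("delay sweep is nonincreasing in delay (both solution paths)", {
  ds <- run_delay_sweep()
  expect_true(all(diff(ds$viability) <= 1e-12))
  ds_pde <- run_delay_sweep(delays = c(0, 4) * HOUR, method = "pde",
                            grid = kinetics_grid(16, 10))
  expect_true(all(diff(ds_pde$viability) <= 1e-12))
  # the two paths agree to the well-mixed-vs-spatial gap
  expect_lt(max(abs(ds_pde$viability - ds$viability[c(1, 3)])), 0.025)
})

test_that("calibration: zero target deficit needs no enzyme release, and the
           deficit grows with k_aga", {
  cal <- calibrate_kaga(1.0)
  expect_identical(cal$k_aga, 0)
  g <- kinetics_grid(10, 6)
  f <- ref_field()
  rpg <- vapply(c(0, 2e-5, 8e-5), function(k) {
    p <- kinetics_params(k_aga = k)
    res <- simulate_kinetics(species_state(g, f), p,
                             treatment_schedule(bath_concentration = 0),
                             t_end = 4 * 86400, dt = 600)
    utils::tail(res$series$relative_pg, 1)
  }, numeric(1))
  expect_true(all(diff(rpg) < 0))
})

test_that("scenario results carry reproducible provenance", {
  r1 <- run_untreated_timecourse(times = c(4, 48) * HOUR)
  r2 <- run_untreated_timecourse(times = c(4, 48) * HOUR)
  expect_identical(attr(r1, "config_hash"), attr(r2, "config_hash"))
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r3 <- run_untreated_timecourse(times = c(4, 48) * HOUR,
                                 params = kinetics_params(k_death = 1e-4))
  expect_false(identical(attr(r1, "config_hash"), attr(r3, "config_hash")))
})

test_that("comparison table tracks all eleven reference scalars", {
  tab <- comparison_table()
  expect_equal(nrow(tab), 11)
  expect_true(all(c("scenario", "reference_value", "model_value", "abs_diff")
                  %in% names(tab)))
  expect_equal(tab$abs_diff, abs(tab$model_value - tab$reference_value))
  # the well-mixed rows should already be close to the references
  expect_lt(max(tab$abs_diff[1:9]), 2.5)
})
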