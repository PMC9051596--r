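# Transport: CSDA ranges, condensed-history stepping, phase-space scoring
# and file round-trips.

test_that("csda_range is anchored, monotone, and quadrature-converged", {
  tab <- fx_table()
  expect_lt(csda_range(tab$energy_keV[1], tab), 1e-6)
  # printed anchor: ~1.76 mm at the beta endpoint energy
  expect_equal(csda_range(497.8, tab), 1760, tolerance = 0.05)
  set.seed(301)
  e <- sort(runif(200, 0.2, 1900))
  r <- csda_range(e, tab)
  expect_true(all(diff(r) > 0))
  expect_error(csda_range(5000, tab), "support")
  expect_error(csda_range(0.01, tab), "support")

  # refined-quadrature oracle: recompute the cumulative integral on a 10x
  # finer grid and compare at interior energies
  fine <- exp(seq(log(0.1), log(2000), length.out = 20000))
  sfine <- stopping_power_at(fine, tab)
  rfine <- cumsum(c(0, (1 / sfine[-1] + 1 / sfine[-length(sfine)]) / 2 * diff(fine)))
  for (ee in c(10, 50, 133.6, 300, 497.8))
    expect_equal(csda_range(ee, tab),
                 approx(fine, rfine, xout = ee)$y, tolerance = 0.01)
})

test_that("ballistic transport reproduces the analytic entry point and range", {
  pop <- fx_pop_small()
  nuc <- central_nucleus(pop)
  med <- medium_cylinder(center_xy = nuc$center[1:2])
  tab <- fx_table()
  st <- transport_settings(scattering_enabled = FALSE, straggling_enabled = FALSE,
                           delta_production_threshold_keV = Inf)
  ev <- list(x = nuc$center[1] - 40, y = nuc$center[2], z = nuc$center[3],
             ux = 1, uy = 0, uz = 0, energy_keV = 200)
  set.seed(302)
  r <- transport_electron(ev, nuc, med, st, tab)
  expect_equal(nrow(r$entries), 1L)
  expect_equal(r$entries$x[1], nuc$center[1] - nuc$half_axes[1], tolerance = 0.01)
  # with all stochastics off, the path length equals the CSDA range
  expect_equal(sum(r$deposits$step_um), csda_range(200, tab), tolerance = 0.01 * csda_range(200, tab))
})

test_that("sub-cutoff electrons deposit locally and energy is conserved", {
  pop <- fx_pop_small()
  nuc <- central_nucleus(pop)
  med <- medium_cylinder(center_xy = nuc$center[1:2])
  tab <- fx_table()
  st <- transport_settings()
  ev <- list(x = 0, y = 0, z = 2, ux = 0, uy = 0, uz = 1, energy_keV = 0.05)
  r0 <- transport_electron(ev, nuc, med, st, tab)
  expect_equal(nrow(r0$deposits), 1L)
  expect_equal(r0$deposits$amount_keV, 0.05)
  expect_equal(nrow(r0$entries), 0L)

  set.seed(303)
  for (i in 1:300) {
    e <- runif(1, 0.2, 480)
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    ev <- list(x = runif(1, -60, 60), y = runif(1, -25, 25), z = runif(1, 0.2, 5.5),
               ux = d[1], uy = d[2], uz = d[3], energy_keV = e)
    r <- transport_electron(ev, nuc, med, st, tab)
    expect_lt(abs(e - (r$deposited_keV + r$escaped_keV)), 1e-6)
    expect_equal(sum(r$deposits$amount_keV), r$deposited_keV, tolerance = 1e-9)
  }
})

test_that("campaigns conserve energy, score boundary entries, and are reproducible", {
  pop <- fx_pop_small()
  sch <- fx_scheme()
  scen <- fx_scenario(internalization_compartment = "cytoplasm")
  cmp <- run_phase_space_campaign(pop, sch, scen, "beta", "cell",
                                  n_primaries = 4000, seed = 304)
  expect_true(nrow(cmp$phase_space) > 0)
  # per-primary conservation
  expect_lt(max(abs(cmp$event_energy_keV -
                    (cmp$event_deposited_keV + cmp$event_escaped_keV))), 1e-6)
  # entry positions lie on the nucleus boundary to 1e-3 um
  nuc <- cmp$nucleus
  rel <- sweep(as.matrix(cmp$phase_space[, c("x_um", "y_um", "z_um")]), 2, nuc$center)
  g <- (rel[, 1] / nuc$half_axes[1])^2 + (rel[, 2] / nuc$half_axes[2])^2 +
       (rel[, 3] / nuc$half_axes[3])^2
  expect_true(all(abs(g - 1) < 5e-3))
  expect_true(all(cmp$phase_space$energy_keV > 0.1))
  # same seed -> byte-identical phase-space files
  cmp2 <- run_phase_space_campaign(pop, sch, scen, "beta", "cell",
                                   n_primaries = 4000, seed = 304)
  f1 <- tempfile(); f2 <- tempfile()
  write_phase_space(cmp, f1); write_phase_space(cmp2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("phase-space files round-trip losslessly to 6 significant digits", {
  pop <- fx_pop_small()
  cmp <- run_phase_space_campaign(pop, fx_scheme(), fx_scenario(), "ic", "cell",
                                  n_primaries = 3000, seed = 305)
  f <- tempfile()
  write_phase_space(cmp, f)
  back <- read_phase_space(f)
  expect_identical(names(back), names(cmp$phase_space))
  expect_identical(back$event_id, cmp$phase_space$event_id)
  for (col in c("x_um", "y_um", "z_um", "ux", "uy", "uz", "energy_keV"))
    expect_equal(back[[col]], cmp$phase_space[[col]], tolerance = 1e-6)
  expect_identical(back$origin_compartment, cmp$phase_space$origin_compartment)
})
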