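# Microdosimetry: specific energy arithmetic, distribution grouping, dose
# identity, reach probability.

test_that("event specific energy is exact unit conversion and linear", {
  # 1 keV in the 811.79 um^3 nucleus
  z1 <- event_specific_energy(1, 811.79)
  expect_equal(z1, 1.602176634e-16 / 8.1179e-13, tolerance = 1e-9)
  expect_equal(event_specific_energy(2, 811.79), 2 * z1, tolerance = 1e-12)
  expect_equal(event_specific_energy(numeric(0), 811.79), 0)
  expect_error(event_specific_energy(1, 0), "positive")
  # z scales inversely with nucleus volume
  expect_equal(event_specific_energy(1, 811.79 / 2), 2 * z1, tolerance = 1e-12)
})

test_that("distribution groups by event, is order-invariant, and dose = sum z", {
  nuc <- nucleus_shape("ellipsoid", c(12, 8.5, 1.9))
  set.seed(401)
  dep <- data.frame(event_id = sample(1:50, 400, replace = TRUE),
                    amount_keV = runif(400, 0.01, 5),
                    in_nucleus = runif(400) < 0.7)
  sed <- specific_energy_distribution(dep, nuc)
  expect_equal(sed$n_events, length(unique(dep$event_id[dep$in_nucleus])))
  expect_equal(sed$z_bar_Gy, mean(sed$z_Gy))
  expect_equal(sed$z_bar_mGy, 1e3 * sed$z_bar_Gy)
  # conservation: sum z * mass = total in-nucleus energy
  expect_equal(sum(sed$z_Gy) * sed$mass_kg / 1.602176634e-16,
               sum(dep$amount_keV[dep$in_nucleus]), tolerance = 1e-9)
  # order invariance under row shuffling
  sed2 <- specific_energy_distribution(dep[sample(nrow(dep)), ], nuc)
  expect_equal(sort(sed2$z_Gy), sort(sed$z_Gy))
  expect_equal(sed2$z_bar_Gy, sed$z_bar_Gy)
  # dose identity, against an independent single-pass summation
  expect_equal(mean_absorbed_dose(dep, nuc), sum(sed$z_Gy), tolerance = 1e-12)
  manual <- sum(dep$amount_keV[dep$in_nucleus]) * 1.602176634e-16 /
    (compartment_volume(nuc) * 1e-15)
  expect_equal(mean_absorbed_dose(dep, nuc), manual, tolerance = 1e-12)
})

test_that("empty distributions are flagged, not invented", {
  nuc <- nucleus_shape("ellipsoid", c(12, 8.5, 1.9))
  dep <- data.frame(event_id = integer(), amount_keV = numeric(), in_nucleus = logical())
  sed <- specific_energy_distribution(dep, nuc)
  expect_equal(sed$n_events, 0L)
  expect_true(is.na(sed$z_bar_Gy))
  expect_equal(mean_absorbed_dose(dep, nuc), 0)
  h <- specific_energy_histogram(sed)
  expect_equal(nrow(h), 0L)
})

test_that("reach probability counts distinct primaries with a Wilson CI", {
  ps <- empty_ps <- data.frame(event_id = integer(0))
  expect_equal(reach_probability(ps, 100)$p, 0)
  all_in <- data.frame(event_id = 1:100)
  expect_equal(reach_probability(all_in, 100)$p, 1)
  # constructed fixture: 250 distinct ids out of 1000 primaries, with repeats
  set.seed(402)
  ids <- c(1:250, sample(1:250, 80, replace = TRUE))
  rp <- reach_probability(data.frame(event_id = ids), 1000)
  expect_equal(rp$p, 0.25)
  expect_equal(rp$n_records, 330L)
  expect_true(rp$ci_low < 0.25 && 0.25 < rp$ci_high)
  expect_error(reach_probability(all_in, 50), "bookkeeping")
  expect_error(reach_probability(all_in, 0), "> 0")
})

test_that("z-bar scales inversely with nucleus volume for identical deposits", {
  set.seed(403)
  dep <- data.frame(event_id = rep(1:20, each = 3), amount_keV = runif(60, 0.1, 2),
                    in_nucleus = TRUE)
  big <- nucleus_shape("elliptic_cylinder", c(8, 11, 2))
  small <- nucleus_shape("elliptic_cylinder", c(8, 11, 1))
  zb <- specific_energy_distribution(dep, big)$z_bar_Gy
  zs <- specific_energy_distribution(dep, small)$z_bar_Gy
  expect_equal(zs, 2 * zb, tolerance = 1e-12)
})
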