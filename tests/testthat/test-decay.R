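# Decay source: beta spectrum sampling, IC lines, emission sites, cumulated
# decays.

test_that("beta sampler respects branch supports and the spectral shape", {
  sch <- fx_scheme()
  set.seed(201)
  e <- sample_beta_energy(sch, 1e5)
  expect_true(all(e > 0))
  expect_true(all(e < max(sch$beta_branches$endpoint_keV)))

  # mean against numerical quadrature of the mixture density
  grid <- seq(0.05, 498.3, by = 0.05)
  dens <- rowSums(sapply(seq_len(nrow(sch$beta_branches)), function(i) {
    d <- beta_spectral_density(grid, sch$beta_branches$endpoint_keV[i], sch$daughter_z)
    sch$beta_branches$probability[i] * d / sum(d * 0.05)
  }))
  mu <- sum(grid * dens * 0.05)
  sd1 <- sqrt(sum(grid^2 * dens * 0.05) - mu^2)
  expect_lt(abs(mean(e) - mu), 3 * sd1 / sqrt(length(e)))

  # Kolmogorov-Smirnov distance against the numerically normalized target
  cdf <- cumsum(dens * 0.05); cdf <- cdf / max(cdf)
  Fhat <- stats::ecdf(e)
  ks <- max(abs(Fhat(grid) - cdf))
  expect_lt(ks, 1.63 / sqrt(length(e)))  # critical value at alpha = 0.01
})

test_that("single-branch histogram matches the closed-form density", {
  sch1 <- decay_scheme(data.frame(endpoint_keV = 300, probability = 1),
                       data.frame(energy_keV = 100, intensity = 1))
  set.seed(202)
  e <- sample_beta_energy(sch1, 2e5)
  expect_true(all(e < 300))
  br <- seq(0, 300, length.out = 31)
  obs <- tabulate(findInterval(e, br, rightmost.closed = TRUE), nbins = 30)
  mids <- (br[-1] + br[-31]) / 2
  d <- beta_spectral_density(mids, 300, 72)
  expprob <- d / sum(d)
  chi2 <- sum((obs - length(e) * expprob)^2 / (length(e) * expprob))
  expect_lt(chi2, 60)  # ~chi2 with 29 df; generous for binning bias
})

test_that("IC line sampling follows intensities", {
  one <- decay_scheme(data.frame(endpoint_keV = 100, probability = 1),
                      data.frame(energy_keV = 100, intensity = 0.15))
  expect_identical(unique(sample_ic_energy(one, 50)), 100)

  set.seed(203)
  two <- decay_scheme(data.frame(endpoint_keV = 100, probability = 1),
                      data.frame(energy_keV = c(50, 150), intensity = c(1, 1)))
  e <- sample_ic_energy(two, 1e5)
  expect_lt(abs(mean(e == 50) - 0.5), 3 * sqrt(0.25 / 1e5))

  three <- decay_scheme(data.frame(endpoint_keV = 100, probability = 1),
                        data.frame(energy_keV = c(10, 20, 70), intensity = c(1, 2, 7)))
  e3 <- sample_ic_energy(three, 1e5)
  for (k in 1:3) {
    p <- c(0.1, 0.2, 0.7)[k]
    expect_lt(abs(mean(e3 == c(10, 20, 70)[k]) - p), 3 * sqrt(p * (1 - p) / 1e5))
  }
  bad <- decay_scheme(data.frame(endpoint_keV = 100, probability = 1),
                      data.frame(energy_keV = 10, intensity = 0))
  expect_error(sample_ic_energy(bad), "zero")
})

test_that("emission sites follow the uptake split and compartment geometry", {
  pop <- fx_pop_small()
  med <- medium_cylinder()
  set.seed(204)
  scen <- fx_scenario(internalization_compartment = "cytoplasm")
  s <- sample_emission_site(scen, pop, med, "cell", 2e4)
  f <- mean(s$origin_compartment == "cytoplasm")
  expect_lt(abs(f - 0.73), 3 * sqrt(0.73 * 0.27 / 2e4))

  # all-membrane scenario: every site in the membrane shell of some cell
  scen_m <- fx_scenario(fraction_internalized = 0)
  sm <- sample_emission_site(scen_m, pop, med, "cell", 300)
  in_shell <- vapply(seq_len(nrow(sm)), function(i) {
    any(vapply(seq_len(pop$n_cells), function(c) {
      p <- c(sm$x[i] - pop$placements[c, 1], sm$y[i] - pop$placements[c, 2], sm$z[i])
      region_contains(pop$cells$membrane, p)
    }, logical(1)))
  }, logical(1))
  expect_true(all(in_shell))

  md <- sample_emission_site(scen, pop, med, "medium", 2e4)
  expect_lt(abs(mean(md$z) - med$height / 2), 3 * (med$height / sqrt(12)) / sqrt(2e4))
  expect_true(all(md$origin_compartment == "medium"))
})

test_that("cumulated decays follow the physical-decay integral", {
  sch <- fx_scheme()
  med <- medium_cylinder()
  lambda <- log(2) / (sch$half_life_h * 3600)

  # short-time limit n -> A0 * t
  scen_short <- fx_scenario(exposure_h = 1e-4, uptake_per_cell = 1,
                            added_activity_MBq_per_mL = 1)
  nd <- cumulated_decays(scen_short, sch, med, n_cells = 1)
  expect_equal(nd$n_C, 1 * 1e-4 * 3600, tolerance = 1e-4)

  # one half-life: n = 0.5 A0 / lambda
  scen_hl <- fx_scenario(exposure_h = sch$half_life_h, uptake_per_cell = 1,
                         added_activity_MBq_per_mL = 1)
  nd_hl <- cumulated_decays(scen_hl, sch, med, n_cells = 1)
  expect_equal(nd_hl$n_C, 0.5 / lambda, tolerance = 1e-9)

  # 4 h value against an independent numeric integral of A(t)
  scen4 <- fx_scenario(exposure_h = 4, uptake_per_cell = 0.7,
                       added_activity_MBq_per_mL = 2.5)
  nd4 <- cumulated_decays(scen4, sch, med, n_cells = 1)
  tt <- seq(0, 4 * 3600, length.out = 40001)
  a <- 0.7 * 2.5 * exp(-lambda * tt)
  numint <- sum((a[-1] + a[-length(a)]) / 2) * diff(tt[1:2])
  expect_equal(nd4$n_C, numint, tolerance = 1e-7)

  # monotone in t and A0, bounded by A0 / lambda
  n1 <- cumulated_decays(fx_scenario(exposure_h = 2, uptake_per_cell = 1), sch, med, 1)$n_C
  n2 <- cumulated_decays(fx_scenario(exposure_h = 8, uptake_per_cell = 1), sch, med, 1)$n_C
  expect_lt(n1, n2)
  expect_lt(n2, 2.5 / lambda)  # A0 = uptake * activity = 2.5 Bq
  expect_error(fx_scenario(exposure_h = -1), "positive")
})
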