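# Geometry module: volumes, containment, sampling, ray crossings, population.

test_that("analytic compartment volumes match closed forms", {
  expect_equal(compartment_volume(nucleus_shape("ellipsoid", c(1, 1, 1))),
               4 * pi / 3, tolerance = 1e-12)
  # the three measured nuclei, to the printed precision
  expect_equal(compartment_volume(nucleus_shape("ellipsoid", c(12, 8.5, 1.9))),
               811.79, tolerance = 1e-4)
  expect_equal(compartment_volume(nucleus_shape("elliptic_cylinder", c(13, 7, 1.25))),
               714.71, tolerance = 1e-4)
  expect_equal(compartment_volume(nucleus_shape("elliptic_cylinder", c(8, 11, 2))),
               1105.84, tolerance = 1e-4)
  expect_error(nucleus_shape("ellipsoid", c(1, -2, 3)), "invalid geometry")
  expect_error(nucleus_shape("ellipsoid", c(0, 2, 3)), "invalid geometry")
})

test_that("analytic volumes agree with Monte Carlo containment estimates", {
  set.seed(101)
  shapes <- list(nucleus_shape("ellipsoid", c(12, 8.5, 1.9)),
                 nucleus_shape("elliptic_cylinder", c(13, 7, 1.25)),
                 region_pball(c(10, 5, 2), p = 1.3),
                 region_elliptic_cylinder(c(9, 4, 2)))
  for (sh in shapes) {
    h <- sh$half_axes
    n <- 2e5
    pts <- cbind(runif(n, -h[1], h[1]), runif(n, -h[2], h[2]), runif(n, -h[3], h[3]))
    inside <- region_contains(sh, pts)
    box <- 8 * prod(h)
    phat <- mean(inside)
    mc <- phat * box
    se <- box * sqrt(phat * (1 - phat) / n)
    expect_lt(abs(mc - compartment_volume(sh)), 3.5 * se)
  }
})

test_that("contains agrees with direct inequality evaluation", {
  nuc <- nucleus_shape("ellipsoid", c(12, 8.5, 1.9), center = c(1, -2, 3))
  expect_true(region_contains(nuc, nuc$center))
  expect_false(region_contains(nuc, nuc$center + c(24, 0, 0)))
  set.seed(102)
  pts <- cbind(runif(1e4, -15, 17), runif(1e4, -12, 9), runif(1e4, 0, 6))
  direct <- ((pts[, 1] - 1) / 12)^2 + ((pts[, 2] + 2) / 8.5)^2 + ((pts[, 3] - 3) / 1.9)^2 <= 1
  expect_identical(unname(region_contains(nuc, pts)), unname(direct))
})

test_that("uniform sampling is centered, contained, and volume-consistent", {
  set.seed(103)
  nuc <- nucleus_shape("ellipsoid", c(12, 8.5, 1.9))
  s <- sample_uniform_point(nuc, 1e5)
  expect_true(all(region_contains(nuc, s)))
  # component means within 3 sigma of the center (sd of a coordinate < a/2)
  for (i in 1:3)
    expect_lt(abs(mean(s[, i])), 3 * nuc$half_axes[i] / 2 / sqrt(1e5))

  ec <- nucleus_shape("elliptic_cylinder", c(13, 7, 1.25))
  s2 <- sample_uniform_point(ec, 1e5)
  # fraction inside the co-axial cylinder with halved footprint axes is 1/4
  inner <- (s2[, 1] / 6.5)^2 + (s2[, 2] / 3.5)^2 <= 1
  expect_lt(abs(mean(inner) - 0.25), 3 * sqrt(0.25 * 0.75 / 1e5))
})

test_that("membrane shell points hug the cytoplasm surface", {
  m <- fx_morph1()
  set.seed(104)
  pts <- sample_uniform_point(m$membrane, 2000)
  expect_true(all(region_contains(m$membrane, pts)))
  expect_false(any(region_contains(m$cytoplasm, pts)))
  # radial distance beyond the surface never exceeds the 0.0075 um thickness
  ctr <- m$cytoplasm$center
  rel <- sweep(pts, 2, ctr)
  r <- sqrt(rowSums(rel^2))
  rs <- region_radius(m$cytoplasm, rel / r)
  expect_true(all(r - rs > 0 & r - rs <= 0.0075 + 1e-9))
})

test_that("nucleus_crossing returns analytic chords and matches ray marching", {
  nuc <- nucleus_shape("ellipsoid", c(12, 8.5, 1.9))
  hit <- nucleus_crossing(nuc, c(-30, 0, 0), c(1, 0, 0))
  expect_equal(hit$chord, 24, tolerance = 1e-9)
  expect_equal(hit$entry, c(-12, 0, 0), tolerance = 1e-9)

  ec <- nucleus_shape("elliptic_cylinder", c(13, 7, 1.25))
  hit2 <- nucleus_crossing(ec, c(0, 0, -10), c(0, 0, 1))
  expect_equal(hit2$chord, 2.5, tolerance = 1e-9)

  expect_null(nucleus_crossing(nuc, c(0, 20, 0), c(1, 0, 0)))
  expect_error(nucleus_crossing(nuc, c(0, 0, 0), c(1, 1, 0)), "unit vector")

  # dense ray-marching oracle on random rays, both nucleus kinds
  set.seed(105)
  for (shape in list(nuc, ec)) {
    for (k in 1:500) {
      p0 <- runif(3, -25, 25)
      d <- rnorm(3); d <- d / sqrt(sum(d^2))
      hit <- nucleus_crossing(shape, p0, d)
      tgrid <- seq(0, 60, by = 0.01)
      inside <- region_contains(shape, outer(tgrid, d) + rep(p0, each = length(tgrid)))
      if (is.null(hit)) {
        expect_lt(sum(inside), 3)  # at most a grazing sliver
      } else {
        expect_lt(abs(sum(inside) * 0.01 - hit$chord), 0.021)  # 0.02 um + grid
      }
    }
  }
})

test_that("population meets confluence exactly, never overlaps, is reproducible", {
  m <- fx_morph1()
  pop <- build_planar_population(m, 50, 0.5, seed = 11)
  expect_equal(pop$n_cells, 50L)
  expect_true(abs(population_confluence(pop) - 0.5) <= 0.05)
  expect_identical(population_overlap_area(pop), 0)
  pop2 <- build_planar_population(m, 50, 0.5, seed = 11)
  expect_identical(pop$placements, pop2$placements)
  pop3 <- build_planar_population(m, 50, 0.5, seed = 12)
  expect_false(identical(pop$placements, pop3$placements))

  p1 <- build_planar_population(m, 1, 0.5, seed = 1)
  expect_equal(p1$central_index, 1L)
  # 7 cells on a 2 x 4 grid cannot cover 95% of the substrate without overlap
  expect_error(build_planar_population(m, 7, 0.95), "overlap|confluence")
})

test_that("morphology surrogates reproduce all measured compartment volumes", {
  printed <- list(c(3465.64, 68.46, 811.79),
                  c(1876.58, 24.34, 714.71),
                  c(4228.08, 63.18, 1105.84))
  for (i in 1:3) {
    m <- table1_morphology(i)
    expect_equal(unname(m$volumes), printed[[i]], tolerance = 0.02)
    # nesting invariants
    set.seed(i)
    nuc_pts <- sample_uniform_point(m$nucleus, 500)
    expect_true(all(region_contains(m$cytoplasm, nuc_pts)))
    gol_pts <- sample_uniform_point(m$golgi, 500)
    expect_true(all(region_contains(m$cytoplasm, gol_pts)))
    expect_false(any(region_contains(m$nucleus, gol_pts)))
    # attached to the dish plane: nothing below z = 0, cytoplasm touches it
    expect_gte(m$cytoplasm$center[3] - m$cytoplasm$half_axes[3], 0)
    expect_lt(m$cytoplasm$center[3] - m$cytoplasm$half_axes[3], 1e-9)
  }
})

test_that("mesh regions: volume by signed tetrahedra, parity containment, sampling", {
  # unit cube shifted to [1,2]^3, written as an OBJ and loaded back
  obj <- tempfile(fileext = ".obj")
  v <- as.matrix(expand.grid(1:2, 1:2, 1:2))
  faces <- rbind(
    c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
    c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
    c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  writeLines(c(sprintf("v %g %g %g", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", faces[, 1], faces[, 2], faces[, 3])), obj)
  mr <- read_mesh_region(obj)
  expect_equal(compartment_volume(mr), 1, tolerance = 1e-9)
  expect_true(region_contains(mr, c(1.5, 1.5, 1.5)))
  expect_false(region_contains(mr, c(0.5, 1.5, 1.5)))
  set.seed(106)
  s <- sample_uniform_point(mr, 500)
  expect_true(all(s >= 1 - 1e-9 & s <= 2 + 1e-9))
})
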