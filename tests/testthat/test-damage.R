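# DNA damage: genome mapping, break induction, DSB clustering rule,
# complexity, yields.

test_that("genome model conserves genomic content and maps every position", {
  nuc <- nucleus_shape("ellipsoid", c(12, 8.5, 1.9))
  g <- genome_model(nuc, total_gbp = 6, voxel_um = 1)
  expect_equal(sum(g$bp), 6e9)
  set.seed(501)
  pts <- sample_uniform_point(nuc, 2000)
  bp <- bp_coordinate(g, pts)
  expect_true(all(bp >= 0 & bp < g$total_bp))
})

test_that("within-voxel offsets follow the 0.34 nm/bp packing arithmetic", {
  nuc <- nucleus_shape("ellipsoid", c(12, 8.5, 1.9))
  g <- genome_model(nuc, voxel_um = 1)
  # two points 1.7 nm apart along a ray from the voxel anchor corner
  base <- c(0.2501, 0.2501, 0.2501)   # inside one voxel
  p2 <- base + c(1.7e-3, 0, 0)        # +1.7 nm along x
  d <- abs(bp_coordinate(g, p2) - bp_coordinate(g, base))
  expect_true(d %in% c(4, 5))  # floor(1.7/0.34) = 5 up to anchor-distance rounding
  p3 <- base + c(3.4e-3, 0, 0)
  expect_lt(abs(bp_coordinate(g, p3) - bp_coordinate(g, base) - 10), 2)
})

test_that("break induction has the right expectation and gating", {
  nuc <- nucleus_shape("ellipsoid", c(12, 8.5, 1.9))
  g <- genome_model(nuc, voxel_um = 1)
  params <- damage_parameters(sb_per_keV = 0.5)
  expect_equal(nrow(induce_strand_breaks(
    data.frame(event_id = integer(), x = numeric(), y = numeric(), z = numeric(),
               amount_keV = numeric(), step_um = numeric()), g, params)), 0L)

  # Poisson-mean oracle: 10 keV deposits repeated many times
  set.seed(502)
  n_rep <- 4000
  dep <- data.frame(event_id = seq_len(n_rep), x = 0, y = 0, z = 0,
                    amount_keV = 10, step_um = 0.35)
  br <- induce_strand_breaks(dep, g, params)
  expected <- 0.5 * 10
  expect_lt(abs(nrow(br) / n_rep - expected), 3 * sqrt(expected * 1.3 / n_rep))
  expect_true(all(br$strand %in% 0:1))
  expect_true(all(br$mechanism %in% c("direct", "indirect")))
  expect_true(all(br$bp_coordinate >= 0 & br$bp_coordinate < g$total_bp))

  # deposits outside the nucleus are skipped and counted
  dep_out <- data.frame(event_id = 1L, x = 50, y = 50, z = 50,
                        amount_keV = 10, step_um = 0.35)
  br_out <- induce_strand_breaks(dep_out, g, params)
  expect_equal(nrow(br_out), 0L)
  expect_equal(attr(br_out, "n_skipped"), 1L)

  # deposits below the direct threshold produce only indirect breaks
  set.seed(503)
  dep_small <- data.frame(event_id = seq_len(3000), x = 0, y = 0, z = 0,
                          amount_keV = 0.01, step_um = 0.05)  # 10 eV < 17.5 eV
  br_small <- induce_strand_breaks(dep_small, g,
                                   damage_parameters(sb_per_keV = 50))
  expect_true(all(br_small$mechanism == "indirect"))
})

test_that("the DSB rule: opposite strands, strict < 10 bp, transitive closure", {
  mk <- function(bp, strand) data.frame(event_id = 1L, bp_coordinate = bp,
                                        strand = strand, mechanism = "direct",
                                        stringsAsFactors = FALSE)
  # separation 5 on opposite strands: one simple DSB
  cl <- cluster_dsbs(mk(c(100, 105), c(0, 1)))
  expect_length(cl, 1)
  expect_equal(classify_complexity(cl[[1]]), "simple")
  # separation 10 is NOT < 10: no DSB
  expect_length(cluster_dsbs(mk(c(100, 110), c(0, 1))), 0)
  # separation 9 clusters
  expect_length(cluster_dsbs(mk(c(100, 109), c(0, 1))), 1)
  # chained opposite-strand pairs form one complex DSB of 3 members
  cl3 <- cluster_dsbs(mk(c(100, 104, 108), c(0, 1, 0)))
  expect_length(cl3, 1)
  expect_equal(nrow(cl3[[1]]), 3L)
  expect_equal(classify_complexity(cl3[[1]]), "complex")
  # single break, or same-strand pair: no DSB
  expect_length(cluster_dsbs(mk(100, 0)), 0)
  expect_length(cluster_dsbs(mk(c(100, 104), c(0, 0))), 0)
  expect_error(classify_complexity(mk(100, 0)), "at least 2")
  expect_error(cluster_dsbs(mk(c(-5, 10), c(0, 1)), genome_bp = 6e9), "range")
})

test_that("clustering matches the brute-force pair-graph oracle", {
  set.seed(504)
  for (rep in 1:500) {
    br <- random_breaks(sample(2:50, 1))
    cl <- cluster_dsbs(br)
    sizes <- sort(vapply(cl, nrow, integer(1)))
    expect_identical(sizes, as.integer(oracle_cluster_sizes(br)))
  }
})

test_that("clustering is permutation- and translation-invariant, and monotone", {
  set.seed(505)
  for (rep in 1:50) {
    br <- random_breaks(30)
    cl <- cluster_dsbs(br)
    n0 <- length(cl)
    # permutation invariance
    expect_length(cluster_dsbs(br[sample(nrow(br)), ]), n0)
    # translation invariance
    br_t <- br; br_t$bp_coordinate <- br_t$bp_coordinate + 12345
    expect_length(cluster_dsbs(br_t), n0)
    # adding a break never destroys an existing DSB: every old cluster's
    # members stay together inside some new cluster (counts can drop only
    # by merging, never by loss)
    extra <- random_breaks(1)
    cl2 <- cluster_dsbs(rbind(br, extra))
    keyset <- lapply(cl2, function(cc) paste(cc$bp_coordinate, cc$strand))
    for (old in cl) {
      ok <- paste(old$bp_coordinate, old$strand)
      expect_true(any(vapply(keyset, function(ks) all(ok %in% ks), logical(1))))
    }
    expect_gte(sum(vapply(cl2, nrow, integer(1))), sum(vapply(cl, nrow, integer(1))))
  }
})

test_that("yield normalization arithmetic and identities", {
  y <- damage_yield(12, n_source_particles = 100, gbp = 6)
  expect_equal(y$per_sp_per_gbp, 0.02)
  expect_equal(y$per_sp, 0.12)
  expect_equal(y$per_sp, 6 * y$per_sp_per_gbp)
  y2 <- damage_yield(12, 100, gbp = 6, mean_dose_per_sp_gy = 0.001)
  expect_equal(y2$per_gy_per_gbp, 0.02 / 0.001)
  # zero dose with nonzero DSBs: per-Gy yield flagged undefined
  y3 <- damage_yield(5, 100, mean_dose_per_sp_gy = 0)
  expect_true(is.na(y3$per_gy_per_gbp))
  expect_error(damage_yield(1, 0), "> 0")
})

test_that("break lists round-trip through the delimited format", {
  br <- random_breaks(25)
  f <- tempfile()
  write_break_list(br, f)
  back <- read_break_list(f)
  expect_equal(back$bp_coordinate, br$bp_coordinate)
  expect_equal(back$strand, br$strand)
  expect_length(cluster_dsbs(back), length(cluster_dsbs(br)))
})

test_that("mean DSB count grows linearly with dose at fixed geometry", {
  nuc <- nucleus_shape("ellipsoid", c(12, 8.5, 1.9))
  g <- genome_model(nuc, voxel_um = 1)
  params <- damage_parameters()
  set.seed(506)
  # synthetic in-nucleus deposit sets of increasing total energy (dose)
  scales <- c(1, 2, 3, 4, 5, 6)
  base_n <- 3000
  n_dsb <- vapply(scales, function(sc) {
    dep <- data.frame(event_id = seq_len(base_n * sc),
                      x = runif(base_n * sc, -6, 6), y = runif(base_n * sc, -4, 4),
                      z = runif(base_n * sc, -0.9, 0.9),
                      amount_keV = 2, step_um = 0.35)
    total <- 0
    for (k in 1:10) total <- total +
      length(cluster_dsbs(induce_strand_breaks(dep, g, params)))
    total / 10
  }, numeric(1))
  fit <- lm(n_dsb ~ scales)
  expect_gt(summary(fit)$r.squared, 0.99)
})
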