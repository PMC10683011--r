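test_that("an ideal-gas target gives a flat profile at the bulk density", {
  fl <- build_fixture("pure_fluid", box_edge = 12, bead_density = 3, seed = 31)
  prof <- pair_correlation(fl, "W", "W", delta_r = 0.05, r_max = 5)
  # beyond r = 1 every bin carries thousands of counts: tight check
  far <- prof[prof$r > 1, ]
  expect_lt(max(abs(far$rho_g - 3) / 3), 0.15)
  expect_equal(mean(prof$rho_g[prof$r >= 2]), 3, tolerance = 0.02)
})

test_that("a two-bead frame fills exactly the bin containing the separation", {
  snap <- snapshot(50, rbind(c(1, 1, 1), c(1, 1, 2.7)), matrix(0, 2, 3),
                   c("A", "B"), 1:2)
  prof <- pair_correlation(snap, "A", "B", delta_r = 0.05, r_max = 3)
  hit <- which(prof$rho_g > 0)
  expect_length(hit, 1)
  d <- 2.7 - 1   # the actual floating-point separation
  expect_equal(hit, floor(d / 0.05) + 1)
  # the single count is normalised by the shell volume
  expect_equal(prof$rho_g[hit], 1 / (4 * pi * prof$r[hit]^2 * 0.05))
})

test_that("simple-cubic neighbour shells match hand enumeration", {
  lat <- build_fixture("lattice", spacing = 1, cells = 5)
  prof <- pair_correlation(lat, "W", "W", delta_r = 0.05, r_max = 2.4)
  counts <- round(prof$rho_g * 4 * pi * prof$r^2 * 0.05)
  # shells of the periodic simple cubic lattice: 6 at 1, 12 at sqrt(2),
  # 8 at sqrt(3), 6 at 2, 24 at sqrt(5)
  shells <- c("1" = 6, "1.414" = 12, "1.732" = 8, "2" = 6, "2.236" = 24)
  for (k in seq_along(shells)) {
    d <- as.numeric(names(shells)[k])
    bin <- floor(sqrt(c(1, 2, 3, 4, 5))[k] / 0.05) + 1
    expect_equal(counts[bin], unname(shells[k]))
  }
  expect_equal(sum(counts), 6 + 12 + 8 + 6 + 24)
})

test_that("coordination integrates the analytic ideal-gas sphere", {
  prof <- flat_profile(0.1, delta_r = 0.05, r_max = 2)
  expect_equal(coordination_number(prof, r_cut = 1),
               0.1 * 4 / 3 * pi, tolerance = 1e-3)   # 0.4189
  # pro-rata handling of a cutoff inside a bin
  z_in <- coordination_number(prof, r_cut = 0.975)
  z_lo <- coordination_number(prof, r_cut = 0.95)
  z_hi <- coordination_number(prof, r_cut = 1.0)
  expect_gt(z_in, z_lo)
  expect_lt(z_in, z_hi)
  # zero-density target
  expect_equal(coordination_number(flat_profile(0), 1), 0)
  expect_error(coordination_number(flat_profile(0.1, r_max = 1), 3),
               class = "dpdmicelle_validation_error")
})

test_that("integration agrees with direct neighbour counting within 1%", {
  fl <- build_fixture("pure_fluid", box_edge = 6, seed = 12)
  run <- dpd_run(fl, water_ff(),
                 integrator_params(n_steps = 400, traj_interval = 100,
                                   seed = 41))
  prof <- pair_correlation(run$frames, "W", "W", delta_r = 0.05, r_max = 2)
  z_int <- coordination_number(prof, r_cut = 1.5)
  z_direct <- direct_coordination(run$frames, "W", "W", r_cut = 1.5)
  expect_equal(z_int, z_direct, tolerance = 0.01)
})

test_that("coordination is additive over disjoint target sets", {
  snap <- build_system(system_config(box_edge = 8, seed = 21))
  zL <- coordination_number(
    pair_correlation(snap, "Proline", "L", r_max = 3.5), 3.45)
  zF <- coordination_number(
    pair_correlation(snap, "Proline", "F", r_max = 3.5), 3.45)
  zLF <- coordination_number(
    pair_correlation(snap, "Proline", c("L", "F"), r_max = 3.5), 3.45)
  expect_equal(zL + zF, zLF)
})

test_that("profiles are invariant under frame permutation", {
  fl <- build_fixture("pure_fluid", box_edge = 5, seed = 2)
  run <- dpd_run(fl, water_ff(),
                 integrator_params(n_steps = 300, traj_interval = 100,
                                   seed = 4))
  p1 <- pair_correlation(run$frames, "W", "W", r_max = 2)
  p2 <- pair_correlation(rev(run$frames), "W", "W", r_max = 2)
  expect_equal(p1$rho_g, p2$rho_g)
})

test_that("profile validation enforces presence and minimum image", {
  fl <- build_fixture("pure_fluid", box_edge = 6, seed = 3)
  expect_error(pair_correlation(fl, "Proline", "W"),
               class = "dpdmicelle_validation_error")
  expect_error(pair_correlation(fl, "W", "W", r_max = 3.2),
               class = "dpdmicelle_validation_error")
})

test_that("contact clustering finds connected chains and separated aggregates", {
  sc <- build_fixture("single_chain", box_edge = 7, seed = 6)
  rep1 <- identify_compartments(sc, contact_cutoff = 1)
  expect_equal(nrow(rep1$clusters), 1)
  expect_equal(rep1$clusters$size, 25)

  # two compact blobs far apart
  blob <- function(center) sweep(matrix(runif(15, -0.3, 0.3), 5, 3), 2,
                                 center, `+`)
  set.seed(9)
  pos <- rbind(blob(c(2, 2, 2)), blob(c(7, 7, 7)))
  snap <- snapshot(10, pos, matrix(0, 10, 3),
                   rep(c("L", "F"), each = 5), rep(1:2, each = 5))
  rep2 <- identify_compartments(snap, contact_cutoff = 1,
                                species_subset = c("L", "F"))
  expect_equal(nrow(rep2$clusters), 2)
  expect_equal(sort(rep2$clusters$size), c(5, 5))
  expect_equal(sum(rep2$clusters$size), 10)
  expect_error(identify_compartments(snap, species_subset = "Q"),
               class = "dpdmicelle_validation_error")
})

test_that("clustering equals the brute-force transitive closure", {
  set.seed(15)
  n <- 150
  snap <- snapshot(5, matrix(runif(3 * n, 0, 5), n, 3), matrix(0, n, 3),
                   sample(c("L", "F", "Proline"), n, replace = TRUE),
                   seq_len(n))
  rep <- identify_compartments(snap, contact_cutoff = 0.8,
                               species_subset = c("L", "F", "Proline"))
  # oracle: O(N^2) adjacency + BFS closure
  pos <- snap$positions
  edges <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- pos[edges[, 1], ] - pos[edges[, 2], ]
  d <- d - 5 * round(d / 5)
  keep <- rowSums(d^2) <= 0.8^2
  memb <- bfs_components(n, edges[keep, , drop = FALSE])
  sizes_oracle <- sort(as.integer(table(memb)))
  expect_equal(sort(rep$clusters$size), sizes_oracle)
  expect_equal(nrow(rep$clusters), length(unique(memb)))
})

test_that("core-shell burial metric distinguishes covered from exposed cores", {
  # an F bead surrounded by six L beads: fully buried
  pos <- rbind(c(5, 5, 5),
               c(5.6, 5, 5), c(4.4, 5, 5), c(5, 5.6, 5),
               c(5, 4.4, 5), c(5, 5, 5.6), c(5, 5, 4.4),
               c(8, 8, 8))
  snap <- snapshot(10, pos, matrix(0, 8, 3),
                   c("F", rep("L", 6), "W"), 1:8)
  expect_equal(core_shell_metric(snap), 1)
  # strip the shell away: the F bead sees only water
  snap2 <- snapshot(10, rbind(c(5, 5, 5), c(5.5, 5, 5)), matrix(0, 2, 3),
                    c("F", "W"), 1:2)
  expect_equal(core_shell_metric(snap2), 0)
})
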