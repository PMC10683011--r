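test_that("pair forces vanish beyond the cutoff and match the soft law inside", {
  ff <- water_ff()
  far <- two_bead_snapshot(1.2)
  f <- pair_forces(far, ff, method = "all")
  expect_equal(max(abs(f$conservative)), 0)
  expect_equal(max(abs(f$dissipative)), 0)
  expect_equal(max(abs(f$random)), 0)

  near <- two_bead_snapshot(0.5)
  f <- pair_forces(near, ff, method = "all")
  # |F^C| = a (1 - r) = 25 * 0.5 on each bead, along x, opposite signs
  expect_equal(f$conservative[1, ], c(-12.5, 0, 0))
  expect_equal(f$conservative[2, ], c(12.5, 0, 0))
  # zero relative velocity kills the dissipative force
  expect_equal(max(abs(f$dissipative)), 0)
  # relative velocity along the bond line turns it on
  moving <- two_bead_snapshot(0.5, velocities = rbind(c(1, 0, 0), c(-1, 0, 0)))
  fm <- pair_forces(moving, ff, method = "all")
  # F^D = -gamma w^2 (e.v_ij) e with e = -x from bead 2 to 1, v_ij = (2,0,0)
  expect_equal(fm$dissipative[1, 1], -4.5 * 0.25 * 2 * 1 * -1 * -1)
  expect_equal(fm$dissipative[1, ], -fm$dissipative[2, ])
})

test_that("every force contribution obeys Newton's third law in aggregate", {
  snap <- build_system(system_config(box_edge = 6, seed = 4))
  ff <- force_field(mcm_chi_table())
  f <- pair_forces(snap, ff, dt = 0.04, seed = 8, step = 5)
  for (part in c("conservative", "dissipative", "random", "bond", "total")) {
    expect_lt(max(abs(colSums(f[[part]]))), 1e-9)
  }
})

test_that("bond forces follow the harmonic law under minimum image", {
  ff <- water_ff(spring_k = 4, spring_r0 = 0.5)
  at_eq <- two_bead_snapshot(0.5, bonds = rbind(c(1L, 2L)))
  expect_equal(max(abs(bond_forces(at_eq, ff))), 0)

  ff0 <- water_ff(spring_k = 4, spring_r0 = 0)
  stretched <- two_bead_snapshot(0.7, bonds = rbind(c(1L, 2L)))
  fb <- bond_forces(stretched, ff0)
  expect_equal(fb[1, ], c(2.8, 0, 0))    # pulled toward its partner
  expect_equal(fb[2, ], c(-2.8, 0, 0))
  # unbonded beads feel no bond force
  expect_equal(max(abs(bond_forces(two_bead_snapshot(0.7), ff0))), 0)
  # bond spanning the periodic boundary uses the minimum image
  wrap <- snapshot(10, rbind(c(0.1, 5, 5), c(9.8, 5, 5)),
                   matrix(0, 2, 3), c("W", "W"), 1:2, rbind(c(1L, 2L)))
  fw <- bond_forces(wrap, ff0)
  expect_equal(fw[1, 1], -4 * 0.3, tolerance = 1e-12)
})

test_that("cell-list forces equal the all-pairs path and an independent oracle", {
  snap <- build_system(system_config(box_edge = 6, seed = 6))  # 648 beads
  ff <- force_field(mcm_chi_table())
  fc <- pair_forces(snap, ff, dt = 0.04, seed = 11, step = 7, method = "cell")
  fa <- pair_forces(snap, ff, dt = 0.04, seed = 11, step = 7, method = "all")
  expect_true(fc$used_cell_list)
  expect_false(fa$used_cell_list)
  for (part in c("conservative", "dissipative", "random", "bond")) {
    expect_lt(max(abs(fc[[part]] - fa[[part]])), 1e-10)
  }
  expect_equal(fc$virial, fa$virial, tolerance = 1e-12)

  ref <- brute_forces(snap, ff, dt = 0.04, seed = 11, step = 7)
  for (part in c("conservative", "dissipative", "random", "bond")) {
    expect_lt(max(abs(fc[[part]] - ref[[part]])), 1e-9)
  }
})

test_that("pair noise is symmetric, reproducible and standardised", {
  expect_identical(pair_noise(5, 3, 10, 20), pair_noise(5, 3, 20, 10))
  expect_identical(pair_noise(5, 3, 10, 20), pair_noise(5, 3, 10, 20))
  expect_false(pair_noise(5, 3, 10, 20) == pair_noise(5, 4, 10, 20))
  expect_false(pair_noise(5, 3, 10, 20) == pair_noise(6, 3, 10, 20))
  draws <- vapply(1:4000, function(k) pair_noise(1, k, 1, 2), numeric(1))
  expect_true(all(abs(draws) <= sqrt(3)))
  expect_lt(abs(mean(draws)), 0.05)
  expect_equal(var(draws), 1, tolerance = 0.1)
})

test_that("free streaming advances positions by v dt exactly", {
  ff <- water_ff()
  snap <- snapshot(10, rbind(c(1, 1, 1), c(8, 8, 8)),
                   rbind(c(0.5, 0.25, 0), c(-0.5, -0.25, 0)),
                   c("W", "W"), 1:2)
  params <- integrator_params(n_steps = 10, dt = 0.04, seed = 1)
  out <- dpd_run(snap, ff, params)$snapshot
  expect_equal(out$positions[1, ], c(1, 1, 1) + 10 * 0.04 * c(0.5, 0.25, 0))
  expect_equal(out$velocities, snap$velocities)
})

test_that("runs are deterministic and a zero-step run is the identity", {
  snap <- build_system(system_config(box_edge = 6, seed = 2))
  ff <- force_field(mcm_chi_table())
  params <- integrator_params(n_steps = 50, thermo_interval = 10, seed = 33)
  r1 <- dpd_run(snap, ff, params)
  r2 <- dpd_run(snap, ff, params)
  expect_identical(r1$snapshot, r2$snapshot)
  expect_identical(r1$thermo, r2$thermo)
  p0 <- integrator_params(n_steps = 0, seed = 33)
  expect_identical(dpd_run(snap, ff, p0)$snapshot, snap)
})

test_that("dissipative and random forces are Galilean invariant", {
  snap <- build_system(system_config(box_edge = 6, seed = 14))
  boosted <- snap
  boosted$velocities <- sweep(snap$velocities, 2, c(-1.3, 0.4, 2.0), `+`)
  ff <- force_field(mcm_chi_table())
  f0 <- pair_forces(snap, ff, dt = 0.04, seed = 3, step = 2)
  f1 <- pair_forces(boosted, ff, dt = 0.04, seed = 3, step = 2)
  expect_equal(f0$conservative, f1$conservative)
  expect_lt(max(abs(f0$dissipative - f1$dissipative)), 1e-9)
  expect_identical(f0$random, f1$random)
})

test_that("total momentum is conserved over long runs", {
  fl <- build_fixture("pure_fluid", box_edge = 6, seed = 5)
  run <- dpd_run(fl, water_ff(),
                 integrator_params(n_steps = 1000, thermo_interval = 50,
                                   seed = 17))
  drift <- max(sqrt(run$thermo$px^2 + run$thermo$py^2 + run$thermo$pz^2))
  expect_lt(drift, 1e-8)
})

test_that("violating fluctuation-dissipation shifts the kinetic temperature", {
  fl <- build_fixture("pure_fluid", box_edge = 6, seed = 8)
  ok <- water_ff()
  hot <- ok
  hot$table$sigma <- 4       # sigma^2 / (2 gamma) = 16/9 -> kT target 1.78
  params <- integrator_params(n_steps = 1200, thermo_interval = 50, seed = 19)
  kT_ok <- mean(tail(tidy(dpd_run(fl, ok, params))$kT, 12))
  kT_hot <- mean(tail(tidy(dpd_run(fl, hot, params))$kT, 12))
  expect_lt(abs(kT_ok - 1), 0.04)
  expect_gt(kT_hot, 1.4)     # clear negative control
})

test_that("diverging integration reports the failing step", {
  snap <- two_bead_snapshot(0.5, velocities = rbind(c(1e308, 0, 0),
                                                    c(-1e308, 0, 0)))
  params <- integrator_params(n_steps = 500, dt = 10, seed = 1)
  expect_error(dpd_run(snap, water_ff(), params), "non-finite")
})

test_that("unknown species raise a configuration error", {
  snap <- two_bead_snapshot(0.5, species = c("W", "X"))
  expect_error(pair_forces(snap, water_ff()),
               class = "dpdmicelle_config_error")
})
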