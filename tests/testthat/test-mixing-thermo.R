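make_records <- function(e_ab, e_ba, e_aa, e_bb, z = 6, v = 100, n = 1) {
  tibble::tibble(
    species_i = c("A", "B", "A", "B"),
    species_j = c("B", "A", "A", "B"),
    Z = z, V_A3 = v, E_kcal_mol = c(e_ab, e_ba, e_aa, e_bb), n = n
  )
}

test_that("ideal mixing gives zero mixing energy and zero chi", {
  rec <- make_records(-1.5, -1.5, -1.5, -1.5)
  expect_equal(mixing_energy(rec, "A", "B"), 0)
  # unlike energetics equal to the mean of unequal like energetics
  rec2 <- make_records(-1.5, -1.5, -1.0, -2.0)
  expect_equal(mixing_energy(rec2, "A", "B"), 0)
  expect_equal(chi_from_mixing(0), 0)
})

test_that("combining rule matches the hand-evaluated value and is linear in E", {
  rec <- make_records(-1.0, -1.0, -2.0, -2.0)
  # hand evaluation: unlike = 6*(-1)/100 = -0.06; like = 6*(-2)/100 = -0.12
  expect_equal(mixing_energy(rec, "A", "B"), 0.06)
  # linearity in the energy fields
  rec2 <- rec
  rec2$E_kcal_mol <- 2 * rec2$E_kcal_mol
  expect_equal(mixing_energy(rec2, "A", "B"), 0.12)
  # 1/n scaling
  rec3 <- rec
  rec3$n <- 4
  expect_equal(mixing_energy(rec3, "A", "B"), 0.015)
  # chi normalisation: V_ref * dE / (R T), evaluated by hand
  ctx <- thermo_context(temperature = 298.15, v_ref = 100)
  expect_equal(chi_from_mixing(0.06, ctx),
               100 * 0.06 / (1.987204258e-3 * 298.15))
})

test_that("chi normalisation hits one when V_ref*dE equals RT", {
  ctx <- thermo_context(temperature = 300, v_ref = 50)
  de <- ctx$gas_constant * 300 / 50
  expect_equal(chi_from_mixing(de, ctx), 1.0)
  # sign follows the mixing energy
  expect_lt(chi_from_mixing(-de, ctx), 0)
})

test_that("packaged water-pentafluorostyrene records round-trip to chi = 0.963", {
  path <- system.file("extdata", "synthetic_mixing_records_fw.csv",
                      package = "dpdmicelle")
  rec <- read_mixing_records(path)
  de <- mixing_energy(rec, "F", "W")
  expect_equal(chi_from_mixing(de, thermo_context()), 0.963, tolerance = 1e-9)
  # and via the table builder
  it <- chi_table_from_records(rec)
  expect_equal(it$chi["F", "W"], 0.963, tolerance = 1e-9)
})

test_that("chi to repulsion map is the density-3 Groot-Warren line", {
  expect_equal(repulsion_from_chi(0), 25)
  expect_equal(repulsion_from_chi(0.963), 28.14901)
  expect_equal(repulsion_from_chi(1.462), 29.78074)
  # affine property on random chi values
  set.seed(42)
  for (k in 1:20) {
    c1 <- runif(1, 0, 5); c2 <- runif(1, 0, 5)
    expect_equal(repulsion_from_chi(c1 + c2) - repulsion_from_chi(c2),
                 repulsion_from_chi(c1) - repulsion_from_chi(0))
  }
  expect_error(repulsion_from_chi(-8), class = "dpdmicelle_validation_error")
  expect_error(repulsion_from_chi(1, density = 4),
               class = "dpdmicelle_validation_error")
})

test_that("packaged chi table matches the published matrix cell by cell", {
  it <- mcm_chi_table()
  expect_identical(it$species, c("L", "H", "F", "Proline", "W"))
  ref <- matrix(c(
    0, 1.462, 0.945, 1.075, 0.756,
    1.462, 0, 0.735, 0.531, 0.197,
    0.945, 0.735, 0, 1.220, 0.963,
    1.075, 0.531, 1.220, 0, 0.459,
    0.756, 0.197, 0.963, 0.459, 0), 5, 5, byrow = TRUE,
    dimnames = list(it$species, it$species))
  expect_equal(it$chi, ref)
  expect_equal(it$chi, t(it$chi))
  expect_equal(unname(diag(it$chi)), rep(0, 5))
  # a-matrix is consistent and invertible back to chi
  expect_equal((it$a - 25) / 3.27, it$chi)
  expect_equal(unname(diag(it$a)), rep(25, 5))
})

test_that("interaction table enforces the fluctuation-dissipation relation", {
  expect_error(interaction_table("W", matrix(0, 1, 1), gamma = 4.5, sigma = 4),
               class = "dpdmicelle_validation_error")
  it <- interaction_table("W", matrix(0, 1, 1), gamma = 4.5)
  expect_equal(it$sigma^2, 2 * it$gamma)
  # asymmetric or non-zero-diagonal chi rejected
  expect_error(interaction_table(c("A", "B"), matrix(c(0, 1, 2, 0), 2)),
               class = "dpdmicelle_validation_error")
  expect_error(interaction_table(c("A", "B"), matrix(c(1, 0, 0, 1), 2)),
               class = "dpdmicelle_validation_error")
})

test_that("record and context validation rejects malformed inputs", {
  rec <- make_records(-1, -1, -2, -2)
  expect_error(mixing_energy(rec[-3, ], "A", "B"),
               class = "dpdmicelle_config_error")
  bad <- rec; bad$V_A3[1] <- -5
  expect_error(mixing_energy(bad, "A", "B"),
               class = "dpdmicelle_validation_error")
  expect_error(thermo_context(temperature = -10),
               class = "dpdmicelle_validation_error")
  expect_error(thermo_context(v_ref = 0),
               class = "dpdmicelle_validation_error")
})

test_that("chi matrices survive a CSV round trip", {
  it <- mcm_chi_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_chi_csv(it, path)
  back <- read_chi_csv(path)
  expect_equal(back$chi, it$chi)
  expect_identical(back$species, it$species)
  # tidy() gives one row per unordered pair
  td <- tidy(it)
  expect_equal(nrow(td), 15)
  expect_equal(td$a, 25 + 3.27 * td$chi)
})
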