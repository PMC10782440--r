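test_that("toy systems are deterministic functions of spec and seed", {
  a <- make_toy_reaction(toy_reaction_spec(n_solvent = 10), seed = 4)
  b <- make_toy_reaction(toy_reaction_spec(n_solvent = 10), seed = 4)
  expect_identical(a$coords, b$coords)
  expect_identical(a$topology, b$topology)
  c_ <- make_toy_reaction(toy_reaction_spec(n_solvent = 10), seed = 5)
  expect_false(identical(a$coords, c_$coords))
})

test_that("toy reaction conserves charge between states", {
  for (cat in c(FALSE, TRUE)) {
    sys <- make_toy_reaction(toy_reaction_spec(n_solvent = 6, catalyst = cat))
    expect_equal(sum(sys$topology$state1$charge),
                 sum(sys$topology$state2$charge), tolerance = 1e-12)
  }
})

test_that("toy topology has nine reacting atoms and state-specific bonds", {
  sys <- make_toy_reaction(toy_reaction_spec(n_solvent = 5))
  expect_equal(sum(sys$topology$atoms$reacting), 9)
  has_bond <- function(st, i, j)
    any((st$bonds$i == i & st$bonds$j == j) | (st$bonds$i == j & st$bonds$j == i))
  expect_true(has_bond(sys$topology$state1, 4, 6))   # breaking bond
  expect_false(has_bond(sys$topology$state1, 0, 8))
  expect_true(has_bond(sys$topology$state2, 0, 8))   # forming bond
  expect_false(has_bond(sys$topology$state2, 4, 6))
})

test_that("the catalyst variant only adds restrained fixed charges", {
  ref <- make_toy_reaction(toy_reaction_spec(n_solvent = 6), seed = 2)
  cat <- make_toy_reaction(toy_reaction_spec(n_solvent = 6, catalyst = TRUE),
                           seed = 2)
  expect_equal(nrow(cat$coords), nrow(ref$coords) + 2)
  # both variants anchor the ring; the catalyst adds its two sites
  expect_equal(nrow(cat$topology$posres), nrow(ref$topology$posres) + 2L)
  # fragment bonded terms are identical
  expect_identical(ref$topology$state1$bonds, cat$topology$state1$bonds)
  expect_identical(ref$topology$state2$bonds, cat$topology$state2$bonds)
  # added charges are equal in both states (spectators of the reaction)
  extra <- 10:11
  expect_identical(cat$topology$state1$charge[extra],
                   cat$topology$state2$charge[extra])
})

test_that("bath particles respect the minimum distance and the sphere", {
  sys <- make_toy_reaction(toy_reaction_spec(n_solvent = 20,
                                             restraint_radius = 8), seed = 7)
  d <- as.matrix(stats::dist(sys$coords))
  diag(d) <- Inf
  solv <- 10:29
  expect_gt(min(d[solv, ]), 2.4)
  expect_true(all(sqrt(rowSums(sys$coords[solv, ]^2)) <= 8))
})

test_that("overcrowded bath placement fails with a data error", {
  expect_error(make_toy_reaction(toy_reaction_spec(n_solvent = 500,
                                                   restraint_radius = 5)),
               class = "evbthermo_data")
})

test_that("oracle presets load and the shape check rejects barrierless diabats", {
  ref <- make_oracle_1d("reference")
  expect_s3_class(ref, "oracle_1d")
  expect_equal(ref$targets$dG_act, 24.5)
  sym <- make_oracle_1d("symmetric")
  expect_equal(sym$coupling$delta_alpha, 0)
  # identical single-well diabats produce no interior barrier
  expect_error(make_oracle_1d(d1 = diabat_1d("harmonic", k = 100, x0 = 0),
                              d2 = diabat_1d("harmonic", k = 100, x0 = 0),
                              coupling = evb_coupling(0, 1),
                              domain = c(-1, 1)),
               class = "evbthermo_data")
})

test_that("the symmetric oracle has zero reaction free energy", {
  sym <- make_oracle_1d("symmetric")
  b <- extract_barriers(oracle_profile_quadrature(sym, 298, bins = 2001))
  expect_lt(abs(b$dG0), 1e-6)
  expect_gt(b$dG_act, 0)
})

test_that("quadrature barriers converge under bin and node refinement", {
  sys <- set_coupling(make_oracle_1d("reference"), calibrated_ref_1d())
  b2 <- extract_barriers(oracle_profile_quadrature(sys, 298, bins = 4001))
  b3 <- extract_barriers(oracle_profile_quadrature(sys, 298, bins = 8001))
  expect_lt(abs(b3$dG_act - b2$dG_act), 0.01)
  # node refinement at fixed bins
  p1 <- oracle_profile_quadrature(sys, 298, bins = 2001)
  p2 <- oracle_profile_quadrature(sys, 298, bins = 2001,
                                  n_nodes = 2L * 200L * 2001L + 1L)
  expect_lt(max(abs(p1$dg - p2$dg)), 2e-3)
})

test_that("Arrhenius fixtures lie exactly on the generating line when noiseless", {
  fx <- arrhenius_fixture(20.9, -3.4 / 298, sigma = 0)
  ser <- make_arrhenius_fixture(fx)
  expect_equal(ser$dG_act, 20.9 + ser$T * 3.4 / 298, tolerance = 1e-12)
  # noisy fixtures are deterministic in the seed
  f1 <- make_arrhenius_fixture(arrhenius_fixture(20.9, -3.4 / 298, sigma = 0.5,
                                                 replicates = 3, seed = 9))
  f2 <- make_arrhenius_fixture(arrhenius_fixture(20.9, -3.4 / 298, sigma = 0.5,
                                                 replicates = 3, seed = 9))
  expect_identical(f1$dG_act, f2$dG_act)
})
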