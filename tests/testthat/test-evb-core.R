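test_that("Morse energy matches the closed form", {
  # D (1 - exp(-a (r - r0)))^2 with D = 100, a = 2, r - r0 = 0.1
  b <- list(D = 100, a = 2, r0 = 1.5)
  expect_equal(morse_energy(1.6, b), 100 * (1 - exp(-0.2))^2,
               tolerance = 1e-12)
  expect_equal(morse_energy(1.5, b), 0)
  # dissociation plateau
  expect_lt(abs(morse_energy(50, b) - 100), 1e-6)
  expect_error(morse_energy(-1, b))
})

test_that("two unit charges at 1 Angstrom give the Coulomb constant", {
  atoms <- data.frame(id = 0:1, mass = 12, reacting = TRUE)
  st <- list(bonds = NULL, angles = NULL, torsions = NULL, impropers = NULL,
             charge = c(1, -1), sigma = c(3, 3), epsilon = c(0, 0))
  topo <- evb_topology(atoms, st, st, coupling = evb_coupling(0, 1))
  x <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  e <- diabatic_energy(x, topo, 1)
  expect_equal(unname(e$terms["rr", "elec"]), -332.0636, tolerance = 1e-10)
  expect_equal(e$total, -332.0636, tolerance = 1e-10)
})

test_that("ground-state energy matches the 2x2 eigenvalue closed form", {
  g <- ground_state_energy(0, 10, evb_coupling(0, 5))
  expect_equal(g$Eg, 5 - sqrt(50), tolerance = 1e-12)
  # weights are the squared ground-eigenvector components
  expect_equal(g$w1 + g$w2, 1, tolerance = 1e-12)
  expect_gt(g$w1, g$w2)  # lower diabat dominates
  # H12 = 0 degenerates to min(eps1, eps2s)
  expect_equal(ground_state_energy(3, 7, evb_coupling(0, 0))$Eg, 3)
})

test_that("ground-state energy is exchange symmetric and bounded above by both diabats", {
  cpl <- evb_coupling(-2, 4)
  e1 <- c(-3, 0, 12.5)
  e2 <- c(5, 0.1, -20)
  a <- ground_state_energy(e1, e2, cpl)
  b <- ground_state_energy(e2, e1, cpl)
  expect_equal(a$Eg, b$Eg, tolerance = 1e-12)
  expect_true(all(a$Eg <= pmin(e1, e2) + 1e-12))
  expect_equal(a$w1, b$w2, tolerance = 1e-12)
})

test_that("increasing the coupling never raises the ground-state energy", {
  H <- seq(0, 25, by = 0.5)
  eg <- vapply(H, function(h) ground_state_energy(1, 4, evb_coupling(0, h))$Eg,
               numeric(1))
  expect_true(all(diff(eg) <= 1e-12))
})

test_that("mapping potential interpolates the diabats at the endpoints", {
  e1 <- c(2, -1); e2s <- c(0.5, 3)
  expect_equal(mapping_energy(e1, e2s, 0), e1)
  expect_equal(mapping_energy(e1, e2s, 1), e2s)
  expect_equal(mapping_energy(e1, e2s, 0.25), 0.75 * e1 + 0.25 * e2s)
  expect_equal(energy_gap(e1, e2s), e1 - e2s)
})

test_that("analytic forces agree with finite differences", {
  sys <- small_toy()
  set.seed(7)
  x <- sys$coords + matrix(rnorm(length(sys$coords), sd = 0.05),
                           nrow(sys$coords))
  for (state in 1:2) {
    fr <- diabatic_forces(x, sys$topology, state)
    num <- fd_forces(sys$topology, x, state)
    expect_lt(max(abs(fr - num)) / max(1, max(abs(num))), 1e-5)
  }
})

test_that("per-term breakdown sums exactly to the total energy", {
  sys <- small_toy()
  set.seed(11)
  x <- sys$coords + matrix(rnorm(length(sys$coords), sd = 0.03),
                           nrow(sys$coords))
  for (state in 1:2) {
    e <- diabatic_energy(x, sys$topology, state)
    expect_lt(abs(sum(e$terms) - e$total), 1e-9)
    expect_identical(rownames(e$terms), c("rr", "rs", "ss"))
    expect_identical(colnames(e$terms),
                     c("bond", "angle", "torsion", "improper", "elec", "vdw"))
  }
})

test_that("exclusions derive from the union bond graph of both states", {
  sys <- make_toy_reaction(toy_reaction_spec(n_solvent = 0))
  ex <- sys$topology$state1$exclusions
  p14 <- sys$topology$state1$pairs14
  # identical in both states by construction
  expect_identical(ex, sys$topology$state2$exclusions)
  has_pair <- function(tab, i, j)
    any((tab$i == i & tab$j == j) | (tab$i == j & tab$j == i))
  # 1-2 via the state-1-only breaking bond (4,6) and state-2-only forming
  # bond (0,8) are both excluded in BOTH states
  expect_true(has_pair(ex, 4, 6))
  expect_true(has_pair(ex, 0, 8))
  # 1-3 through the ring
  expect_true(has_pair(ex, 0, 2))
  # 1-4 through the ring is scaled, not excluded
  expect_true(has_pair(p14, 0, 3))
  expect_false(has_pair(ex, 0, 3))
})

test_that("topology validation rejects malformed input", {
  atoms <- data.frame(id = 0:1, mass = 12, reacting = TRUE)
  st <- list(bonds = NULL, angles = NULL, torsions = NULL, impropers = NULL,
             charge = c(0, 0), sigma = c(3, 3), epsilon = c(0.1, 0.1))
  bad <- st; bad$charge <- c(0, 0, 0)
  expect_error(evb_topology(atoms, bad, st, coupling = evb_coupling(0, 1)))
  bad2 <- st
  bad2$bonds <- data.frame(i = 0, j = 5, D = 100, a = 2, r0 = 1.5)
  expect_error(evb_topology(atoms, bad2, st, coupling = evb_coupling(0, 1)),
               "atom")
  expect_error(evb_coupling(0, -1))
})

test_that("set_coupling accepts a coupling or a calibration result", {
  sys <- make_oracle_1d("reference")
  s2 <- set_coupling(sys, evb_coupling(-5, 2))
  expect_equal(s2$coupling$delta_alpha, -5)
  expect_equal(s2$coupling$H12, 2)
  fake_cal <- structure(list(delta_alpha = -1.5, H12 = 4,
                             achieved = NULL, iterations = 0L,
                             trace = NULL, converged = TRUE),
                        class = "calibration_result")
  s3 <- set_coupling(sys, fake_cal)
  expect_equal(s3$coupling$H12, 4)
})
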