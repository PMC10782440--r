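test_that("decomposition aggregates satisfy their defining arithmetic", {
  terms <- c(bond = 110, angle = 0.4, torsion = -0.2, improper = 0.1,
             elec = 1, vdw = -0.3)
  d <- activation_decomposition(terms, dU_rr = 108, dU_rs = 3.1)
  expect_equal(d$dU_bonded, 110.3)
  expect_equal(d$dU_nonbond, 0.7)
  expect_equal(d$dU_tot_r, d$dU_bonded + d$dU_nonbond, tolerance = 1e-12)
  expect_equal(d$dU_tot_r, sum(terms), tolerance = 1e-12)
  expect_error(activation_decomposition(c(bond = 1, elec = 2)))
  expect_output(print(d), "dU_tot_r")
})

test_that("state selection and decomposition run end to end on a sampled toy", {
  sys <- small_toy(seed = 3, n_solvent = 8)
  cfg <- quick_config(seed = 6, steps = 6000)
  wins <- suppressWarnings(run_fep_protocol(sys, 298, 61, 1, cfg))
  fep <- suppressWarnings(fep_cumulative(wins))
  prof <- umbrella_profile(wins, fep, bins = 41)
  sel <- select_state_frames(wins, prof, halfwidth = 2)
  expect_s3_class(sel$RS, "state_frames")
  expect_gte(sel$RS$n, 20)
  expect_gte(sel$TS$n, 20)
  # ground-state weights are proper probabilities
  expect_true(all(sel$TS$w1 >= 0 & sel$TS$w1 <= 1))
  expect_equal(sel$TS$w1 + sel$TS$w2, rep(1, sel$TS$n), tolerance = 1e-9)
  # the ensembles are ordered along the gap: RS (low-gap side) below TS
  expect_lt(mean(sel$RS$de), mean(sel$TS$de))

  dec <- decompose_activation(sel$RS, sel$TS)
  expect_equal(dec$dU_tot_r, dec$dU_rr + dec$dU_rs, tolerance = 1e-9)
  expect_equal(unname(dec$terms),
               unname(dec$per_group$rr + dec$per_group$rs), tolerance = 1e-9)
  expect_true(all(is.finite(dec$terms)))
})

test_that("windows sampled without breakdowns are rejected", {
  sys <- make_oracle_1d("reference")
  cfg <- quick_config(seed = 2, steps = 2000)
  wins <- suppressWarnings(run_fep_protocol(sys, 298, 21, 1, cfg))
  fep <- suppressWarnings(fep_cumulative(wins))
  prof <- umbrella_profile(wins, fep, bins = 31)
  expect_error(select_state_frames(wins, prof), "breakdown")
})

test_that("geometry observables match hand-computed values", {
  # 5 atoms in a column-per-frame coordinate matrix; one frame
  xyz <- c(0, 0, 0,   1, 0, 0,   1, 1, 0,   2, 1, 0,  1, 1, 1)
  crd <- matrix(xyz, ncol = 1)
  g <- measure_geometry(crd, list(
    distances = list(d01 = c(0, 1), d02 = c(0, 2)),
    torsions = list(phi = c(0, 1, 2, 3), chi = c(0, 1, 2, 4))))
  expect_equal(g$series$d01, 1)
  expect_equal(g$series$d02, sqrt(2))
  expect_equal(g$series$phi, 180)   # trans backbone
  expect_equal(abs(g$series$chi), 90, tolerance = 1e-9)
  expect_identical(g$means$type, c("distance", "distance", "torsion", "torsion"))
  # collinear backbone has no defined torsion
  lin <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0, 3, 0, 0), ncol = 1)
  expect_error(measure_geometry(lin, list(torsions = list(t = 0:3))),
               "collinear")
  expect_error(measure_geometry(crd, list(distances = list(bad = c(0, 9)))),
               "invalid")
})

test_that("TS frames of the toy reaction show the forming bond contracted", {
  sys <- small_toy(seed = 3, n_solvent = 8)
  cfg <- quick_config(seed = 6, steps = 6000)
  cfg$record_coords <- TRUE
  wins <- suppressWarnings(run_fep_protocol(sys, 298, 61, 1, cfg))
  fep <- suppressWarnings(fep_cumulative(wins))
  prof <- umbrella_profile(wins, fep, bins = 41)
  sel <- select_state_frames(wins, prof, halfwidth = 2)
  defs <- list(distances = list(forming = c(0, 8)))
  d_rs <- measure_geometry(sel$RS, defs)$means$mean
  d_ts <- measure_geometry(sel$TS, defs)$means$mean
  expect_lt(d_ts, d_rs)
})
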