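test_that("sampling is bit-identical for a fixed seed and differs across seeds", {
  sys <- make_oracle_1d("reference")
  cfg <- quick_config(seed = 11, steps = 500)
  w1 <- suppressWarnings(run_fep_protocol(sys, 298, 5, 1, cfg))
  w2 <- suppressWarnings(run_fep_protocol(sys, 298, 5, 1, cfg))
  expect_identical(lapply(w1, `[[`, "frames"), lapply(w2, `[[`, "frames"))
  cfg3 <- quick_config(seed = 12, steps = 500)
  w3 <- suppressWarnings(run_fep_protocol(sys, 298, 5, 1, cfg3))
  expect_false(identical(w1[[1]]$frames, w3[[1]]$frames))
})

test_that("frames satisfy the mapping-potential identity", {
  sys <- small_toy()
  cfg <- quick_config(seed = 2, steps = 500)
  st <- equilibrate(sys, cfg, lambda = 0.3, seed = 2)
  w <- run_window(sys, 0.3, 298, cfg, st, seed = 5)
  fr <- w$frames
  expect_lt(max(abs(fr$eps_m - (0.7 * fr$eps1 + 0.3 * fr$eps2s))), 1e-9)
  # Eg below both diabats
  expect_true(all(fr$Eg <= pmin(fr$eps1, fr$eps2s) + 1e-9))
  # breakdowns recorded and consistent with the stored diabatic energies
  expect_equal(rowSums(w$breakdown1), fr$eps1, tolerance = 1e-9)
  expect_equal(rowSums(w$breakdown2) + sys$topology$coupling$delta_alpha,
               fr$eps2s, tolerance = 1e-9)
})

test_that("equilibration ramps six stages from 1 K and reaches the target", {
  sys <- small_toy()
  cfg <- quick_config(seed = 4)
  st <- equilibrate(sys, cfg, lambda = 0, seed = 4)
  log <- attr(st, "log")
  expect_equal(nrow(log), 6)
  expect_equal(log$temperature, seq(1, 298, length.out = 6))
  expect_true(attr(st, "reached"))
})

test_that("a single particle in a harmonic well equilibrates near 298 K", {
  # 1 degree of freedom: long trailing average needed for a tight bound
  sym <- make_oracle_1d("symmetric")
  cfg <- simulation_config(seed = 1)
  cfg$n_equil_steps <- c(200L, 200L, 200L, 200L, 200L, 40000L)
  st <- equilibrate(sym, cfg, lambda = 0, seed = 1)
  kin <- attr(st, "log")$kinT_trailing[6]
  expect_gte(kin, 268)
  expect_lte(kin, 328)
})

test_that("long-run kinetic temperature matches the bath within 2 percent", {
  sys <- small_toy()
  cfg <- quick_config(seed = 9, steps = 20000)
  st <- equilibrate(sys, cfg, lambda = 0.5, seed = 9)
  w <- run_window(sys, 0.5, 298, cfg, st, seed = 10)
  expect_lt(abs(mean(w$frames$kinT) - 298) / 298, 0.02)
})

test_that("zero-friction integration conserves total energy", {
  sys <- small_toy()
  cfg <- quick_config(seed = 5)
  st <- equilibrate(sys, cfg, lambda = 0.5, seed = 9)
  cfg$friction_ps <- 0
  cfg$timestep_fs <- 0.5
  cfg$sample_stride <- 1L
  w <- run_window(sys, 0.5, 298, cfg, st, seed = 13, n_steps = 8000)
  etot <- w$frames$ekin + w$frames$eps_m + w$frames$e_restraint
  span_ps <- 8000 * 0.5 / 1000
  drift <- abs(etot[length(etot)] - etot[1]) / span_ps
  expect_lt(drift, 0.01)  # kcal/mol/ps
})

test_that("Maxwell velocities reproduce the target temperature statistics", {
  m <- rep(c(12, 18, 40), each = 400)
  v <- evbthermo:::cpp_maxwell_velocities(m, 298, 21L)
  kb <- evb_constants()$kB
  # per-component variance kT/m, pooled over many atoms
  z <- sqrt(m) * v / sqrt(kb * 298)
  expect_lt(abs(sd(as.numeric(z)) - 1), 0.05)
  expect_lt(abs(mean(as.numeric(z))), 0.05)
})

test_that("a failing replicate aborts with a warning and others continue", {
  sys <- make_oracle_1d("reference")
  cfg <- quick_config(seed = 3, steps = 300)
  cfg$timestep_fs <- 200  # unstable for replicate dynamics
  expect_error(suppressWarnings(run_fep_protocol(sys, 298, 5, 2, cfg)),
               class = "evbthermo_numerical")
})

test_that("config validation rejects nonsense", {
  expect_error(simulation_config(timestep_fs = -1))
  expect_error(simulation_config(n_equil_steps = c(1, 2, 3)))
  expect_error(simulation_config(temperature = 0))
})
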