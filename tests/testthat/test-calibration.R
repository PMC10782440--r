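test_that("calibration targets validate their fields", {
  t <- calibration_targets(24.5, -12.8, 0.3, 298)
  expect_s3_class(t, "calibration_targets")
  expect_error(calibration_targets(tolerance = 0))
  expect_error(calibration_targets(temperature = -5))
})

test_that("quadrature calibration closes on the 1D reference oracle", {
  cal <- calibrated_ref_1d()
  expect_true(cal$converged)
  expect_lt(abs(cal$achieved$dG_act - 24.5), 1e-3)
  expect_lt(abs(cal$achieved$dG0 + 12.8), 1e-3)
  # trace records every evaluated iterate
  expect_true(all(c("iter", "delta_alpha", "H12", "dG_act", "dG0") %in%
                    names(cal$trace)))
  expect_gte(nrow(cal$trace), 2)
  # residuals of the recorded iterates improve from start to end
  r_first <- abs(cal$trace$dG_act[1] - 24.5) + abs(cal$trace$dG0[1] + 12.8)
  r_last <- abs(cal$trace$dG_act[nrow(cal$trace)] - 24.5) +
    abs(cal$trace$dG0[nrow(cal$trace)] + 12.8)
  expect_lt(r_last, r_first)
})

test_that("calibration is deterministic", {
  c1 <- calibrate_evb(make_oracle_1d("reference"),
                      calibration_targets(24.5, -12.8, 0.3, 298))
  c2 <- calibrate_evb(make_oracle_1d("reference"),
                      calibration_targets(24.5, -12.8, 0.3, 298))
  expect_identical(c1$delta_alpha, c2$delta_alpha)
  expect_identical(c1$H12, c2$H12)
})

test_that("sampling-path calibration converges within the stochastic tolerance", {
  sys <- make_oracle_1d("reference")
  cal <- suppressWarnings(
    calibrate_evb(sys, calibration_targets(24.5, -12.8, 0.3, 298),
                  config = quick_config(seed = 17, steps = 4000),
                  method = "sampling", n_windows = 21, n_replicates = 3))
  expect_true(cal$converged)
  expect_lt(abs(cal$achieved$dG_act - 24.5),
            0.3 + 2 * cal$achieved$sem_act + 1e-9)
  expect_lt(abs(cal$achieved$dG0 + 12.8), 0.3 + 2 * cal$achieved$sem0 + 1e-9)
})

test_that("non-convergence raises a classed error carrying the trace", {
  sys <- make_oracle_1d("reference")
  err <- tryCatch(
    calibrate_evb(sys, calibration_targets(2.0, -80, 0.001, 298),
                  max_iter = 3),
    error = function(e) e)
  expect_s3_class(err, "evbthermo_no_convergence")
  expect_s3_class(err, "evbthermo_numerical")
  expect_true(is.data.frame(attr(err, "trace")) || is.data.frame(err$trace))
})

test_that("a calibration result can be applied to a system directly", {
  cal <- calibrated_ref_1d()
  sys <- set_coupling(make_oracle_1d("reference"), cal)
  expect_equal(sys$coupling$delta_alpha, cal$delta_alpha)
  prof <- oracle_profile_quadrature(sys, 298, bins = 4001)
  b <- extract_barriers(prof)
  expect_lt(abs(b$dG_act - cal$achieved$dG_act), 1e-9)
})
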