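test_that("a noiseless fixture is recovered to machine precision", {
  fx <- arrhenius_fixture(dH = 18.0, dS = -0.01, sigma = 0)
  fit <- fit_arrhenius(make_arrhenius_fixture(fx), n_boot = 10L)
  expect_equal(fit$dH_act, 18.0, tolerance = 1e-10)
  expect_equal(fit$dS_act, -0.01, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # Gibbs relation at the reference temperature
  g <- thermo_at_temperature(fit, 298)
  expect_equal(g$dG_act, 18.0 + 298 * 0.01, tolerance = 1e-10)
})

test_that("temperature series validation rejects bad input", {
  ok <- data.frame(T = c(288, 298, 308), replicate = 1, dG_act = c(1, 2, 3))
  expect_s3_class(temperature_series(ok), "temperature_series")
  expect_error(temperature_series(ok[1:2, ]), "3 distinct")
  bad <- ok; bad$dG_act[2] <- NA
  expect_error(temperature_series(bad), "finite")
  bad2 <- ok; bad2$T[1] <- -5
  expect_error(temperature_series(bad2), "positive")
})

test_that("bootstrap standard errors are seeded and deterministic", {
  fx <- arrhenius_fixture(20.9, -3.4 / 298, sigma = 0.3, replicates = 8,
                          seed = 5)
  ser <- make_arrhenius_fixture(fx)
  f1 <- fit_arrhenius(ser, n_boot = 200L, boot_seed = 42L)
  f2 <- fit_arrhenius(ser, n_boot = 200L, boot_seed = 42L)
  expect_identical(f1$se_dH, f2$se_dH)
  f3 <- fit_arrhenius(ser, n_boot = 200L, boot_seed = 43L)
  expect_false(identical(f1$se_dH, f3$se_dH))
  expect_gt(f1$se_dH, 0)
  # bootstrap does not perturb the point estimates
  expect_identical(f1$dH_act, f3$dH_act)
})

test_that("fit operates on per-temperature means, not raw replicates", {
  # duplicate replicates must not change the point estimate
  d <- data.frame(T = rep(c(288, 298, 308), each = 2),
                  replicate = rep(1:2, 3),
                  dG_act = rep(c(20, 20.3, 20.6), each = 2))
  f_dup <- fit_arrhenius(temperature_series(d), n_boot = 10L)
  f_one <- fit_arrhenius(temperature_series(d[d$replicate == 1, ]),
                         n_boot = 10L)
  expect_equal(f_dup$dH_act, f_one$dH_act, tolerance = 1e-12)
})

test_that("printing and plotting a fit work without errors", {
  fit <- fit_arrhenius(make_arrhenius_fixture(arrhenius_fixture(20.9, -3.4 / 298)),
                       n_boot = 10L)
  expect_output(print(fit), "dH_act")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(fit))
})

test_that("thermo_at_temperature rejects nonpositive temperatures", {
  f <- structure(list(dH_act = 10, dS_act = 0), class = "arrhenius_fit")
  expect_error(thermo_at_temperature(f, 0), "positive")
})
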