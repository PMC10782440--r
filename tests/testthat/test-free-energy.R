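test_that("FEP increments are exact for a constant perturbation", {
  # when eps2s - eps1 is the same constant c in every frame of every window,
  # dG(lambda) = -lambda * (eps1 - eps2s) = lambda * c with no noise
  cpl <- evb_coupling(0, 1)
  mk <- function(lam) fake_window(lam, eps1 = rep(2, 50), eps2s = rep(5, 50),
                                  coupling = cpl)
  wins <- lapply(seq(0, 1, by = 0.25), mk)
  fep <- fep_cumulative(wins)
  expect_equal(fep$dG_cum, seq(0, 1, by = 0.25) * 3, tolerance = 1e-12)
  expect_equal(fep$dG_fwd, -fep$dG_bwd, tolerance = 1e-12)
})

test_that("forward and backward estimates are averaged", {
  set.seed(1)
  e1a <- rnorm(400); e1b <- rnorm(400, 0.3)
  w1 <- fake_window(0.0, e1a, e1a - 1)
  w2 <- fake_window(0.5, e1b, e1b - 1)
  fep <- fep_cumulative(list(w1, w2))
  expect_equal(fep$dG_cum[2], 0.5 * (fep$dG_fwd[1] - fep$dG_bwd[1]),
               tolerance = 1e-12)
})

test_that("FEP refuses mixed replicates and starved windows", {
  w1 <- fake_window(0, rnorm(50), rnorm(50), replicate = 1L)
  w2 <- fake_window(1, rnorm(50), rnorm(50), replicate = 2L)
  expect_error(fep_cumulative(list(w1, w2)), "replicate")
  w3 <- fake_window(1, rnorm(5), rnorm(5))
  expect_error(fep_cumulative(list(w1, w3)), "frames")
})

test_that("umbrella profile reproduces an analytic single-window limit", {
  # lambda = 0 window: eps_m = eps1, so the reweighting factor is
  # exp(-beta (Eg - eps1)); with H12 -> 0 and eps2s >> eps1, Eg == eps1 and
  # the profile is just the sampled histogram free energy
  kb <- evb_constants()$kB
  set.seed(3)
  # keep de << 0 so eps2s stays far above eps1 and Eg == eps1 on every frame
  de <- rnorm(1e5, mean = -10, sd = 2)
  eps1 <- rep(0, length(de))
  w <- fake_window(0, eps1, eps1 - de, coupling = evb_coupling(0, 1e-8))
  fep <- structure(list(lambda = 0, dG_cum = 0, temperature = 298),
                   class = "fep_result")
  prof <- umbrella_profile(list(w), fep, bins = 21)
  # expected: -kT log p(de), normalized at the minimum
  expected <- -kb * 298 * (stats::dnorm(prof$de_center, -10, 2, log = TRUE) -
                             stats::dnorm(-10, -10, 2, log = TRUE))
  # only well-populated bins: multinomial noise is kT/sqrt(n) per bin
  keep <- prof$n_frames > 2000
  expect_lt(max(abs(prof$dg[keep] - (expected[keep] - min(expected[keep])))),
            0.05)
})

test_that("bins below the frame threshold are masked", {
  set.seed(5)
  de <- c(rnorm(2000), rnorm(4, 10))  # stray frames far to the right
  w <- fake_window(0, rep(0, length(de)), -de, coupling = evb_coupling(0, 1e-8))
  fep <- structure(list(lambda = 0, dG_cum = 0, temperature = 298),
                   class = "fep_result")
  prof <- umbrella_profile(list(w), fep, bins = seq(-4, 11, by = 0.5),
                           min_frames = 10)
  expect_true(all(prof$n_frames >= 10))
  expect_lt(max(prof$de_center), 8)  # stray cluster trimmed
})

test_that("a genuine sampling gap raises a numerical error", {
  set.seed(6)
  de <- c(rnorm(1000, -10), rnorm(1000, 10))  # two disconnected basins
  w <- fake_window(0, rep(0, length(de)), -de, coupling = evb_coupling(0, 1e-8))
  fep <- structure(list(lambda = 0, dG_cum = 0, temperature = 298),
                   class = "fep_result")
  expect_error(umbrella_profile(list(w), fep, bins = 41),
               class = "evbthermo_numerical")
})

test_that("barrier extraction picks the most prominent interior maximum", {
  dg <- c(0, 2, 1, 6, 2.5, 3, -4)
  prof <- free_energy_profile(seq_along(dg), dg)
  b <- extract_barriers(prof)
  expect_equal(b$ts, 4)
  expect_equal(b$dG_act, 6)
  expect_equal(b$dG0, -4)
  # monotonic profile has no barrier
  expect_error(extract_barriers(free_energy_profile(1:5, c(0, 1, 2, 3, 4))),
               class = "evbthermo_numerical")
})

test_that("landmark ties break toward the lower energy gap", {
  dg <- c(0, 5, 1, 5, 0)
  lm <- evbthermo:::find_landmarks(dg)
  expect_equal(lm$ts, 2)
  expect_equal(lm$rs, 1)
})

test_that("profiles are normalized to zero at the reactant minimum", {
  sys <- set_coupling(make_oracle_1d("reference"), evb_coupling(-12.8, 7.3))
  prof <- oracle_profile_quadrature(sys, 298, bins = 501)
  lm <- evbthermo:::find_landmarks(prof$dg)
  expect_equal(prof$dg[lm$rs], 0, tolerance = 1e-12)
  expect_lt(prof$de_center[lm$rs], prof$de_center[lm$ps])
})

test_that("replicate barriers aggregate mean and SEM over replicates", {
  sys <- set_coupling(make_oracle_1d("reference"), calibrated_ref_1d())
  wins <- suppressWarnings(
    run_fep_protocol(sys, 298, 21, 3, quick_config(seed = 8, steps = 4000)))
  rb <- replicate_barriers(wins)
  expect_equal(nrow(rb$per_replicate), 3)
  expect_equal(rb$summary$mean[1], mean(rb$per_replicate$dG_act),
               tolerance = 1e-12)
  expect_true(all(is.finite(rb$summary$sem)))
  expect_length(rb$profiles, 3)
})
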