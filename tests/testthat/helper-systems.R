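# Shared fixtures; everything here is deterministic.

# small config for mechanics-oriented tests (statistics tests set their own)
quick_config <- function(seed = 1L, steps = 2000L, ...) {
  cfg <- simulation_config(seed = seed, ...)
  cfg$n_prod_steps <- as.integer(steps)
  cfg$n_equil_steps <- c(50L, 50L, 50L, 50L, 50L, 200L)
  cfg$window_equil_steps <- 50L
  cfg
}

# calibrated coupling of the 1D reference oracle, computed once per session
calibrated_ref_1d <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cal <- calibrate_evb(make_oracle_1d("reference"),
                           calibration_targets(24.5, -12.8, 0.3, 298))
      cache <<- cal
    }
    cache
  }
})

# tiny solvated toy for force/energy mechanics
small_toy <- function(seed = 3L, n_solvent = 8L) {
  make_toy_reaction(toy_reaction_spec(n_solvent = n_solvent), seed = seed)
}

withr_tempfile <- function(ext) tempfile(fileext = ext)

# numeric gradient of the diabatic energy
fd_forces <- function(topo, coords, state, h = 1e-5) {
  num <- matrix(NA_real_, nrow(coords), 3)
  for (i in seq_len(nrow(coords))) {
    for (k in 1:3) {
      xp <- coords; xm <- coords
      xp[i, k] <- xp[i, k] + h
      xm[i, k] <- xm[i, k] - h
      num[i, k] <- -(diabatic_energy(xp, topo, state)$total -
                       diabatic_energy(xm, topo, state)$total) / (2 * h)
    }
  }
  num
}

# hand-built window (bypasses the sampler) for estimator unit tests
fake_window <- function(lambda, eps1, eps2s, coupling = evb_coupling(0, 1),
                        temperature = 298, replicate = 1L) {
  g <- ground_state_energy(eps1, eps2s, coupling)
  frames <- data.frame(step = seq_along(eps1), eps1 = eps1, eps2s = eps2s,
                       Eg = g$Eg,
                       eps_m = (1 - lambda) * eps1 + lambda * eps2s,
                       kinT = temperature)
  evbthermo:::window_obj(lambda = lambda, temperature = temperature,
                         replicate = replicate, frames = frames,
                         coupling = coupling)
}
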