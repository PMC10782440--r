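#' 1D diabat specification
#'
#' Parameterizes a one-dimensional diabatic potential, either a harmonic
#' well 0.5*k*(x - x0)^2 + offset or a Morse well
#' D*(1 - exp(-a*(x - x0)))^2 + offset.
#'
#' @param form "harmonic" or "morse".
#' @param k,D,a,x0,offset Parameters (kcal/mol, 1/A, A as appropriate).
#' @return Numeric coding vector understood by the 1D engine.
#' @export
diabat_1d <- function(form = c("harmonic", "morse"), k = NULL, D = NULL,
                      a = NULL, x0 = 0, offset = 0) {
  form <- match.arg(form)
  if (form == "harmonic") {
    stopifnot(!is.null(k), k > 0)
    c(0, k, x0, offset)
  } else {
    stopifnot(!is.null(D), D > 0, !is.null(a), a > 0)
    c(1, D, a, x0, offset)
  }
}

diabat_value <- function(d, x) as.numeric(cpp_pot1d(d, x))

oracle_reactant_x <- function(system) {
  if (system$d1[1] == 0) system$d1[3] else system$d1[4]
}

#' One-dimensional oracle reaction system
#'
#' Builds a two-state 1D system whose free-energy profile along the energy
#' gap is computable to arbitrary accuracy by quadrature
#' ([oracle_profile_quadrature()]), making it an exact reference for the
#' sampled FEP/umbrella pipeline. Two presets ship with the package:
#' `"reference"` (an asymmetric system standing in for the uncatalyzed
#' solution reaction; calibrating its coupling to targets of 24.5 / -12.8
#' kcal/mol succeeds) and `"symmetric"` (mirror-image diabats, zero shift,
#' hence a reaction free energy of exactly zero).
#'
#' @param preset Preset name, or `NULL` when `d1`/`d2` are given.
#' @param d1,d2 Diabats from [diabat_1d()].
#' @param coupling An [evb_coupling()].
#' @param domain Length-2 sampling domain (A).
#' @param mass Particle mass (amu).
#' @param label System label.
#' @return Object of class `oracle_1d`.
#' @export
make_oracle_1d <- function(preset = c("reference", "symmetric"), d1 = NULL,
                           d2 = NULL, coupling = NULL, domain = NULL,
                           mass = 12, label = NULL) {
  if (is.null(d1)) {
    preset <- match.arg(preset)
    path <- system.file("extdata", paste0("oracle_", preset, "_1d.json"),
                        package = "evbthermo")
    js <- jsonlite::read_json(path, simplifyVector = TRUE)
    from_js <- function(d) do.call(diabat_1d, as.list(d))
    sys <- structure(list(d1 = from_js(js$diabat1), d2 = from_js(js$diabat2),
                          coupling = evb_coupling(js$coupling$delta_alpha,
                                                  js$coupling$H12),
                          domain = as.numeric(js$domain), mass = js$mass,
                          label = js$label,
                          targets = js$targets),
                     class = "oracle_1d")
  } else {
    stopifnot(!is.null(d2), !is.null(coupling), !is.null(domain))
    sys <- structure(list(d1 = d1, d2 = d2, coupling = coupling,
                          domain = as.numeric(domain), mass = mass,
                          label = label %||% "custom", targets = NULL),
                     class = "oracle_1d")
  }
  check_oracle_shape(sys)
  sys
}

# the ground surface must show two minima separated by one interior maximum
check_oracle_shape <- function(sys) {
  x <- seq(sys$domain[1], sys$domain[2], length.out = 2001)
  eg <- oracle_ground_energy(sys, x)
  d <- diff(eg)
  sign_changes <- diff(sign(d))
  n_min <- sum(sign_changes > 0)
  n_max <- sum(sign_changes < 0)
  if (n_min < 2 || n_max < 1)
    stop_data("diabats do not produce two minima and an interior barrier on the domain")
  invisible(TRUE)
}

oracle_ground_energy <- function(sys, x) {
  e1 <- diabat_value(sys$d1, x)
  e2s <- diabat_value(sys$d2, x) + sys$coupling$delta_alpha
  ground_state_energy(e1, e2s, sys$coupling)$Eg
}

#' Exact free-energy profile of a 1D oracle by quadrature
#'
#' Integrates the Boltzmann weight of the ground-state surface over a dense
#' coordinate grid and bins it along the energy gap, giving a sampling-free
#' reference profile: dg(de_n) = -kB T log sum_{x in bin n} exp(-beta Eg(x)) dx,
#' normalized at the reactant minimum.
#'
#' @param system An `oracle_1d`.
#' @param temperature Temperature (K).
#' @param bins Number of gap bins, or explicit bin edges (to compare with a
#'   sampled profile, pass its edges).
#' @param n_nodes Quadrature nodes across the domain; defaults to at least
#'   200 nodes per bin. Bin masses are obtained by interpolating the
#'   cumulative Boltzmann weight at the bin edges, so they vary smoothly
#'   with the edge positions rather than jumping by whole node weights.
#' @return An `evb_profile` (column `n_frames` holds node counts).
#' @export
oracle_profile_quadrature <- function(system, temperature = 298, bins = 1001L,
                                      n_nodes = NULL) {
  stopifnot(inherits(system, "oracle_1d"))
  beta <- 1 / (.KB * temperature)
  nb_req <- if (length(bins) == 1L) bins else length(bins) - 1L
  # keep >= 200 nodes per bin: with few nodes per bin the integer node count
  # itself perturbs each bin integral by ~kT/nodes-per-bin
  if (is.null(n_nodes)) n_nodes <- max(20001L, as.integer(200L * nb_req) + 1L)
  x <- seq(system$domain[1], system$domain[2], length.out = n_nodes)
  e1 <- diabat_value(system$d1, x)
  e2s <- diabat_value(system$d2, x) + system$coupling$delta_alpha
  eg <- ground_state_energy(e1, e2s, system$coupling)$Eg
  de <- e1 - e2s
  if (length(bins) == 1L) {
    edges <- seq(min(de), max(de), length.out = bins + 1L)
  } else {
    edges <- sort(as.numeric(bins))
  }
  nb <- length(edges) - 1L
  mx <- max(-beta * eg)
  w <- exp(-beta * eg - mx)
  # each node's mass is spread over the gap interval between its neighbors'
  # midpoints; nodes straddling a bin edge contribute fractionally to both
  # bins. Bin masses then vary continuously with the edge positions (no
  # whole-node granularity, and symmetric systems stay exactly symmetric)
  # while each bin keeps a locally summed (full-precision) mass.
  o <- order(de)
  des <- de[o]; ws <- w[o]
  n <- length(des)
  bp <- c(des[1], 0.5 * (des[-1] + des[-n]), des[n])
  lo <- findInterval(bp[-(n + 1)], edges, rightmost.closed = TRUE)
  hi <- findInterval(bp[-1], edges, rightmost.closed = TRUE)
  simple <- lo == hi & lo >= 1 & lo <= nb
  sums <- as.numeric(tapply(ws[simple],
                            factor(lo[simple], levels = seq_len(nb)),
                            sum, default = 0))
  for (i in which(lo != hi)) {
    l <- bp[i]; r <- bp[i + 1]
    if (r <= l) {
      if (lo[i] >= 1 && lo[i] <= nb) sums[lo[i]] <- sums[lo[i]] + ws[i]
      next
    }
    for (j in max(lo[i], 1L):min(hi[i], nb)) {
      ov <- min(r, edges[j + 1]) - max(l, edges[j])
      if (ov > 0) sums[j] <- sums[j] + ws[i] * ov / (r - l)
    }
  }
  bin <- findInterval(de, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin[bin >= 1 & bin <= nb], nb)
  dg <- ifelse(sums > 0, -(log(sums) + mx) / beta, NA_real_)
  if (!any(is.finite(dg))) stop_numerical("quadrature produced no finite bins")
  ok <- which(is.finite(dg))
  span <- ok[1]:ok[length(ok)]
  # interior empty bins only arise from non-monotone gap maps with
  # pathological binning; interpolate across single-node gaps
  if (anyNA(dg[span])) {
    nas <- span[is.na(dg[span])]
    dg[nas] <- stats::approx(span[!span %in% nas], dg[span[!span %in% nas]],
                             xout = nas)$y
  }
  centers <- 0.5 * (edges[-1] + edges[-length(edges)])
  prof <- free_energy_profile(centers[span], dg[span], counts[span],
                              temperature = temperature,
                              edges = edges[c(span, span[length(span)] + 1L)])
  normalize_profile(prof)
}

#' Toy 3D reaction specification
#'
#' Describes the desk-scale analog of a condensed-phase rearrangement: a
#' nine-atom reacting fragment (a six-ring plus a three-atom arm) with a
#' state-1 Morse bond that breaks (the C5-O7 analog, ring atom 4 to arm atom
#' 6) and a state-2 Morse bond that forms (the C1-C9 analog, ring atom 0 to
#' arm atom 8), state-dependent fragment charges, a monoatomic
#' Lennard-Jones bath inside a flat-bottom spherical restraint, and an
#' optional "catalyst" variant that only adds fixed, position-restrained
#' charges placed to stabilize the product-like charge distribution near the
#' forming bond (net charge conserved between states in both variants).
#'
#' @param n_solvent Number of LJ bath particles.
#' @param restraint_radius,restraint_k Flat-bottom sphere (A, kcal/mol/A^2).
#' @param catalyst Add the fixed stabilizing charges.
#' @param solvent_sigma,solvent_epsilon,solvent_mass LJ bath parameters.
#' @return Object of class `toy_reaction_spec`.
#' @export
toy_reaction_spec <- function(n_solvent = 20L, restraint_radius = 8,
                              restraint_k = 10, catalyst = FALSE,
                              solvent_sigma = 3.1, solvent_epsilon = 0.15,
                              solvent_mass = 18) {
  stopifnot(n_solvent >= 0, restraint_radius > 0, restraint_k >= 0)
  structure(list(n_solvent = as.integer(n_solvent),
                 restraint_radius = restraint_radius,
                 restraint_k = restraint_k, catalyst = isTRUE(catalyst),
                 solvent_sigma = solvent_sigma,
                 solvent_epsilon = solvent_epsilon,
                 solvent_mass = solvent_mass),
            class = "toy_reaction_spec")
}

#' Build a toy 3D reaction system
#'
#' Deterministic construction from a spec and a seed (the seed only places
#' the bath particles). Bond lengths and angle references of terms common to
#' both states are taken from the built reactant geometry, so the reactant
#' state is strain-free by construction. The ring is position-restrained in
#' the lab frame in both variants (as an active site would hold a
#' substrate); the arm, which carries the reaction coordinate, is not.
#' The bath avoids the catalyst sites in both variants, so a same-seed
#' reference/catalyst pair shares identical coordinates and differs only in
#' the added fixed charges.
#'
#' @param spec A [toy_reaction_spec()] (or preset name `"reference"` /
#'   `"catalyst"`, read from the shipped preset files).
#' @param seed Integer seed for bath placement.
#' @return Object of class `evb_system`: list with `topology`
#'   ([evb_topology()]), `coords`, `label`, `spec`.
#' @export
make_toy_reaction <- function(spec = toy_reaction_spec(), seed = 1L) {
  if (is.character(spec)) {
    path <- system.file("extdata", paste0("toy_", spec, ".json"),
                        package = "evbthermo")
    js <- jsonlite::read_json(path, simplifyVector = TRUE)
    coupling <- evb_coupling(js$coupling$delta_alpha, js$coupling$H12)
    label <- js$label
    spec <- do.call(toy_reaction_spec, js$spec)
  } else {
    coupling <- evb_coupling(-10, 3)
    label <- if (spec$catalyst) "toy-catalyst" else "toy-reference"
  }
  stopifnot(inherits(spec, "toy_reaction_spec"))
  frag <- toy_fragment_geometry()
  n_frag <- nrow(frag$coords)

  coords <- frag$coords
  masses <- rep(12, n_frag)
  reacting <- rep(TRUE, n_frag)
  q1 <- numeric(n_frag); q2 <- numeric(n_frag)
  # state 1: dipole across the breaking bond (atoms 4, 6; 1-based indices)
  q1[5] <- 0.25; q1[7] <- -0.25
  # state 2: bond formation polarizes the rigid ring core, +0.25 at the
  # forming-bond site (atom 0) and -0.25 diametrically opposite (atom 3).
  # Placing the product charges on ring atoms (not the mobile arm tip)
  # keeps the state-2 charge geometry the same in every ensemble, so an
  # external field acts on it identically at RS and TS.
  q2[1] <- 0.25; q2[4] <- -0.25
  sig <- rep(3.0, n_frag); eps <- rep(0.10, n_frag)
  # anchor the rigid ring (atoms 0-5) in the lab frame in BOTH variants,
  # as an active site would hold a substrate: without this the fragment
  # tumbles and diffuses inside the container, so the fixed catalyst
  # charges see an ill-defined fragment geometry and the comparison
  # drowns in diffusion noise. The arm (atoms 6-8) stays unrestrained --
  # it carries the reaction coordinate.
  ring_ids <- 0:5
  posres <- data.frame(atom = ring_ids, k = 5,
                       x = coords[ring_ids + 1, 1],
                       y = coords[ring_ids + 1, 2],
                       z = coords[ring_ids + 1, 3])

  # fixed-charge catalyst sites: an anion parked just outside the ring next
  # to the forming-bond site (atom 0, which carries the product-like +0.25),
  # clear of the arm-tip approach corridor; its interaction with the rigid
  # product charge pattern is essentially constant in geometry, so it lowers
  # the state-2 surface uniformly (product-state stabilization). The
  # counter-cation sits far away. The bath avoids these sites in BOTH
  # variants so that a reference/catalyst pair with the same seed shares
  # identical coordinates and differs only in the added fixed charges.
  p_minus <- coords[1, ] + c(2.8, 0, -0.65)
  p_plus <- c(-5.5, 5.5, 3.0)

  if (spec$catalyst) {
    coords <- rbind(coords, p_minus, p_plus)
    masses <- c(masses, 40, 40)
    reacting <- c(reacting, FALSE, FALSE)
    q1 <- c(q1, -1, 1); q2 <- c(q2, -1, 1)
    sig <- c(sig, 3.0, 3.0); eps <- c(eps, 0.10, 0.10)
    posres <- rbind(posres,
                    data.frame(atom = c(n_frag, n_frag + 1L), k = 20,
                               x = c(p_minus[1], p_plus[1]),
                               y = c(p_minus[2], p_plus[2]),
                               z = c(p_minus[3], p_plus[3])))
  }

  if (spec$n_solvent > 0) {
    obstacles <- rbind(frag$coords, p_minus, p_plus)
    solv <- with_rng(seed, place_solvent(obstacles, spec$n_solvent,
                                         spec$restraint_radius - 1, 2.4))
    coords <- rbind(coords, solv)
    masses <- c(masses, rep(spec$solvent_mass, spec$n_solvent))
    reacting <- c(reacting, rep(FALSE, spec$n_solvent))
    q1 <- c(q1, rep(0, spec$n_solvent)); q2 <- c(q2, rep(0, spec$n_solvent))
    sig <- c(sig, rep(spec$solvent_sigma, spec$n_solvent))
    eps <- c(eps, rep(spec$solvent_epsilon, spec$n_solvent))
  }

  n <- nrow(coords)
  atoms <- data.frame(id = 0:(n - 1L), mass = masses, reacting = reacting)
  mk_state <- function(bonds, q) {
    terms <- derive_bonded_terms(bonds, frag$coords)
    list(bonds = terms$bonds, angles = terms$angles, torsions = terms$torsions,
         impropers = frag$improper, charge = q, sigma = sig, epsilon = eps)
  }
  topo <- evb_topology(
    atoms,
    state1 = mk_state(rbind(frag$bonds_common, frag$bond_break), q1),
    state2 = mk_state(rbind(frag$bonds_common, frag$bond_form), q2),
    coupling = coupling,
    restraint = list(center = c(0, 0, 0), radius = spec$restraint_radius,
                     k = spec$restraint_k),
    posres = posres)
  structure(list(topology = topo, coords = unname(coords), label = label,
                 spec = spec), class = "evb_system")
}

# nine-atom fragment: planar-ish six-ring (atoms 0-5) + arm 6-7-8 attached
# at ring atom 4; atom 8 poised above ring atom 0 where the new bond forms
toy_fragment_geometry <- function() {
  ring <- t(vapply(0:5, function(k)
    c(1.5 * cos(pi / 3 * k), 1.5 * sin(pi / 3 * k), 0.05 * (-1)^k),
    numeric(3)))
  a4 <- ring[5, ]
  a6 <- a4 + 1.45 * a4 / sqrt(sum(a4^2)) + c(0, 0, 0.25)
  # near-attack conformation: the arm tip is built 2.7 A from ring atom 0,
  # above the ring plane and tilted toward the arm base so that two 1.5 A
  # bonds can reach it. The phase-aligned torsions derived from this
  # geometry hold the arm here, so the reactant ensemble is pre-organized
  # for attack and the free-energy maximum along the gap coincides with
  # the diabatic crossing (a mixed, half-product-like transition state)
  # rather than with a conformational-search bottleneck.
  a0 <- ring[1, ]
  up <- c(-0.5, -0.45, 0.74)
  a8 <- a0 + 2.7 * up / sqrt(sum(up^2))
  mid <- (a6 + a8) / 2
  h <- a8 - a6
  perp <- c(-h[2], h[1], 0); perp <- perp / sqrt(sum(perp^2))
  off <- sqrt(1.5^2 - sum(h^2) / 4)
  c1 <- mid + off * perp; c2 <- mid - off * perp
  # place atom 7 on the branch farther from the ring axis (no crowding)
  a7 <- if (sum(c1[1:2]^2) > sum(c2[1:2]^2)) c1 else c2
  coords <- rbind(ring, a6, a7, a8)
  bonds_common <- rbind(
    cbind(0:5, c(1:5, 0)),          # ring
    c(6, 7), c(7, 8))               # arm
  list(coords = coords,
       bonds_common = bonds_common,
       bond_break = matrix(c(4, 6), 1),   # state-1 only
       bond_form = matrix(c(0, 8), 1),    # state-2 only
       improper = data.frame(i = 5L, j = 0L, k = 1L, l = 2L, k_xi = 5,
                             xi0 = dihedral_deg(coords[6, ], coords[1, ],
                                                coords[2, ], coords[3, ]) * pi / 180))
}

# bonds: Morse terms with r0 from the built geometry except the forming bond
# (r0 = 1.55 A, its product equilibrium length); angles/torsions enumerated
# from the bond graph with reference values from the geometry
derive_bonded_terms <- function(bond_pairs, coords) {
  bp <- matrix(as.integer(bond_pairs), ncol = 2)
  n_frag <- nrow(coords)
  dist <- function(i, j) sqrt(sum((coords[i + 1, ] - coords[j + 1, ])^2))
  bonds <- data.frame(i = bp[, 1], j = bp[, 2], D = 100, a = 2, r0 = NA_real_)
  for (t in seq_len(nrow(bonds))) {
    i <- bonds$i[t]; j <- bonds$j[t]
    is_react_bond <- (i == 4 && j == 6) || (i == 0 && j == 8)
    bonds$D[t] <- if (is_react_bond) 80 else 100
    bonds$r0[t] <- if (i == 0 && j == 8) 1.55 else dist(i, j)
  }
  adj <- vector("list", n_frag)
  for (t in seq_len(nrow(bp))) {
    adj[[bp[t, 1] + 1]] <- c(adj[[bp[t, 1] + 1]], bp[t, 2])
    adj[[bp[t, 2] + 1]] <- c(adj[[bp[t, 2] + 1]], bp[t, 1])
  }
  ang <- list(); tor <- list()
  for (j in 0:(n_frag - 1)) {
    nb <- adj[[j + 1]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(nb, 2)
      for (c_ in seq_len(ncol(cmb)))
        ang[[length(ang) + 1]] <- c(cmb[1, c_], j, cmb[2, c_])
    }
  }
  for (t in seq_len(nrow(bp))) {
    j <- bp[t, 1]; k <- bp[t, 2]
    for (i in setdiff(adj[[j + 1]], k)) for (l in setdiff(adj[[k + 1]], j))
      if (i != l) tor[[length(tor) + 1]] <- c(i, j, k, l)
  }
  angle_val <- function(i, j, k) {
    u <- coords[i + 1, ] - coords[j + 1, ]; v <- coords[k + 1, ] - coords[j + 1, ]
    acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
  }
  angles <- if (length(ang)) {
    m <- do.call(rbind, ang)
    data.frame(i = m[, 1], j = m[, 2], k = m[, 3], k_theta = 40,
               theta0 = vapply(seq_len(nrow(m)), function(t) {
                 # angles created by the forming bond pull toward tetrahedral
                 if (any(m[t, ] == 8L) && any(m[t, ] == 0L)) 1.911
                 else angle_val(m[t, 1], m[t, 2], m[t, 3])
               }, numeric(1)))
  } else empty_angles()
  torsions <- if (length(tor)) {
    m <- do.call(rbind, tor)
    phi0 <- vapply(seq_len(nrow(m)), function(t)
      dihedral_deg(coords[m[t, 1] + 1, ], coords[m[t, 2] + 1, ],
                   coords[m[t, 3] + 1, ], coords[m[t, 4] + 1, ]) * pi / 180,
      numeric(1))
    # phases aligned so the built geometry is a torsional minimum:
    # V = k(1 + cos(n*phi - delta)) is minimal at phi0 for delta = n*phi0 - pi
    data.frame(i = m[, 1], j = m[, 2], k = m[, 3], l = m[, 4],
               k_phi = 1.5, n = 3L, delta = 3 * phi0 - pi)
  } else empty_torsions()
  list(bonds = bonds, angles = angles, torsions = torsions)
}

place_solvent <- function(existing, n, radius, min_dist) {
  out <- matrix(NA_real_, n, 3)
  placed <- existing
  for (k in seq_len(n)) {
    ok <- FALSE
    for (try in 1:2000) {
      p <- stats::runif(3, -radius, radius)
      if (sum(p^2) > radius^2) next
      d2 <- rowSums((placed - matrix(p, nrow(placed), 3, byrow = TRUE))^2)
      if (all(d2 > min_dist^2)) { ok <- TRUE; break }
    }
    if (!ok) stop_data("overlapping initial coordinates: cannot place bath particle %d", k)
    out[k, ] <- p
    placed <- rbind(placed, p)
  }
  out
}

#' Arrhenius fixture with prescribed enthalpy/entropy
#'
#' @param dH Generating activation enthalpy (kcal/mol).
#' @param dS Generating activation entropy (kcal/mol/K).
#' @param temperatures Temperature ladder (K); the default six points span
#'   288-313 K in 5 K steps.
#' @param sigma Gaussian noise on each replicate dG_act (kcal/mol).
#' @param replicates Replicates per temperature.
#' @param seed Seed; the fixture is a pure function of (parameters, seed)
#'   and exactly on the generating line when `sigma = 0`.
#' @return Object of class `arrhenius_fixture`.
#' @export
arrhenius_fixture <- function(dH, dS, temperatures = seq(288, 313, by = 5),
                              sigma = 0, replicates = 1L, seed = 1L) {
  stopifnot(length(temperatures) >= 3, sigma >= 0, replicates >= 1)
  structure(list(dH = dH, dS = dS, temperatures = as.numeric(temperatures),
                 sigma = sigma, replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "arrhenius_fixture")
}

#' Materialize an Arrhenius fixture into a temperature series
#'
#' Generates replicate activation free energies
#' dG_act(T) = dH - T * dS + noise on the fixture's temperature ladder.
#'
#' @param fixture An [arrhenius_fixture()].
#' @param label System label for the series.
#' @return A [temperature_series()].
#' @export
make_arrhenius_fixture <- function(fixture, label = "fixture") {
  stopifnot(inherits(fixture, "arrhenius_fixture"))
  grid <- expand.grid(replicate = seq_len(fixture$replicates),
                      T = fixture$temperatures)
  noise <- if (fixture$sigma > 0) {
    with_rng(fixture$seed, stats::rnorm(nrow(grid), sd = fixture$sigma))
  } else rep(0, nrow(grid))
  temperature_series(
    data.frame(T = grid$T, replicate = grid$replicate,
               dG_act = fixture$dH - grid$T * fixture$dS + noise),
    label = label)
}
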