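#' Two-state EVB topologies
#'
#' An EVB system is described by two diabatic force fields (a reactant-like
#' state 1 and a product-like state 2) that share one atom set but differ in
#' their bonded terms and charges, plus a constant coupling. The constructor
#' validates both states, derives nonbonded exclusions from the bond graph
#' (1-2 and 1-3 pairs excluded, 1-4 pairs scaled by 0.5 for both
#' electrostatics and van der Waals), and returns an object consumed by the
#' energy evaluators and the sampler.
#'
#' Exclusions are derived from the union of the two states' bond graphs, so a
#' forming or breaking bond pair is excluded from the nonbonded sums in both
#' states; the Morse terms alone describe those pairs. No nonbonded cutoff is
#' applied anywhere. Lennard-Jones cross terms use geometric means for both
#' sigma and epsilon.
#'
#' @param atoms data.frame with columns `id` (0-based, contiguous), `mass`
#'   (amu) and `reacting` (logical; member of the reacting fragment).
#' @param state1,state2 Per-state force fields: a list with elements
#'   `bonds` (data.frame `i,j,D,a,r0`: Morse wells, kcal/mol, 1/A, A),
#'   `angles` (`i,j,k,k_theta,theta0`: harmonic, kcal/mol/rad^2, rad;
#'   energy 0.5*k*(theta-theta0)^2),
#'   `torsions` (`i,j,k,l,k_phi,n,delta`: k*(1+cos(n*phi-delta))),
#'   `impropers` (`i,j,k,l,k_xi,xi0`: harmonic 0.5*k*(xi-xi0)^2),
#'   `charge`, `sigma`, `epsilon` (per-atom vectors; e, A, kcal/mol).
#'   Missing term tables default to empty.
#' @param coupling An [evb_coupling()] object.
#' @param restraint Optional flat-bottom spherical restraint applied to all
#'   atoms: list with `center` (length-3), `radius` (A), `k` (kcal/mol/A^2).
#' @param posres Optional per-atom harmonic position restraints: data.frame
#'   with columns `atom`, `k`, `x`, `y`, `z`.
#'
#' @return An object of class `evb_topology`.
#' @export
evb_topology <- function(atoms, state1, state2,
                         coupling = evb_coupling(0, 0),
                         restraint = NULL, posres = NULL) {
  stopifnot(is.data.frame(atoms), all(c("id", "mass", "reacting") %in% names(atoms)))
  n <- nrow(atoms)
  if (n < 1L) stop("topology needs at least one atom")
  if (!identical(sort(as.integer(atoms$id)), 0:(n - 1L)))
    stop("atom ids must be unique and contiguous from 0")
  atoms <- atoms[order(atoms$id), , drop = FALSE]
  if (any(atoms$mass <= 0)) stop("atom masses must be positive")
  atoms$reacting <- as.logical(atoms$reacting)
  if (!any(atoms$reacting)) stop("at least one atom must be flagged reacting")

  state1 <- validate_state(state1, n, "state1")
  state2 <- validate_state(state2, n, "state2")
  stopifnot(inherits(coupling, "evb_coupling"))

  # exclusions from the union bond graph of both states
  adj <- union_adjacency(state1$bonds, state2$bonds, n)
  ex <- derive_exclusions(adj, n)
  state1$exclusions <- ex$excl
  state2$exclusions <- ex$excl
  state1$pairs14 <- ex$p14
  state2$pairs14 <- ex$p14

  if (!is.null(restraint)) {
    stopifnot(length(restraint$center) == 3, restraint$radius > 0, restraint$k >= 0)
    restraint <- list(center = as.numeric(restraint$center),
                      radius = as.numeric(restraint$radius),
                      k = as.numeric(restraint$k))
  }
  if (!is.null(posres)) {
    stopifnot(is.data.frame(posres),
              all(c("atom", "k", "x", "y", "z") %in% names(posres)),
              all(posres$atom >= 0 & posres$atom < n))
  }
  structure(list(atoms = atoms, state1 = state1, state2 = state2,
                 coupling = coupling, restraint = restraint, posres = posres),
            class = "evb_topology")
}

empty_bonds <- function() data.frame(i = integer(), j = integer(),
                                     D = numeric(), a = numeric(), r0 = numeric())
empty_angles <- function() data.frame(i = integer(), j = integer(), k = integer(),
                                      k_theta = numeric(), theta0 = numeric())
empty_torsions <- function() data.frame(i = integer(), j = integer(), k = integer(),
                                        l = integer(), k_phi = numeric(),
                                        n = integer(), delta = numeric())
empty_impropers <- function() data.frame(i = integer(), j = integer(), k = integer(),
                                         l = integer(), k_xi = numeric(),
                                         xi0 = numeric())

validate_state <- function(s, n, label) {
  s$bonds <- if (is.null(s$bonds)) empty_bonds() else as.data.frame(s$bonds)
  s$angles <- if (is.null(s$angles)) empty_angles() else as.data.frame(s$angles)
  s$torsions <- if (is.null(s$torsions)) empty_torsions() else as.data.frame(s$torsions)
  s$impropers <- if (is.null(s$impropers)) empty_impropers() else as.data.frame(s$impropers)
  ids <- c(s$bonds$i, s$bonds$j, s$angles$i, s$angles$j, s$angles$k,
           s$torsions$i, s$torsions$j, s$torsions$k, s$torsions$l,
           s$impropers$i, s$impropers$j, s$impropers$k, s$impropers$l)
  if (length(ids) && (any(ids < 0) || any(ids >= n)))
    stop(label, ": bonded term references an invalid atom id")
  if (nrow(s$bonds)) {
    if (any(s$bonds$i == s$bonds$j)) stop(label, ": bond atom pair not distinct")
    if (any(s$bonds$D <= 0) || any(s$bonds$a <= 0) || any(s$bonds$r0 <= 0))
      stop(label, ": Morse parameters D, a, r0 must be positive")
    s$bonds$i <- as.integer(s$bonds$i); s$bonds$j <- as.integer(s$bonds$j)
  }
  if (nrow(s$angles)) {
    if (any(s$angles$k_theta < 0)) stop(label, ": angle force constants must be >= 0")
    if (any(s$angles$theta0 < 0 | s$angles$theta0 > pi))
      stop(label, ": theta0 must lie in [0, pi]")
  }
  if (nrow(s$torsions) && (any(s$torsions$n < 1) || any(s$torsions$k_phi < 0)))
    stop(label, ": torsions need n >= 1 and k_phi >= 0")
  if (nrow(s$impropers) && any(s$impropers$k_xi < 0))
    stop(label, ": improper force constants must be >= 0")
  for (f in c("charge", "sigma", "epsilon")) {
    if (is.null(s[[f]])) s[[f]] <- rep(if (f == "sigma") 1 else 0, n)
    if (length(s[[f]]) != n) stop(label, ": ", f, " must have one entry per atom")
  }
  if (any(s$sigma <= 0)) stop(label, ": sigma must be positive")
  if (any(s$epsilon < 0)) stop(label, ": epsilon must be >= 0")
  for (int_col in c("i", "j")) s$bonds[[int_col]] <- as.integer(s$bonds[[int_col]])
  s$torsions$n <- as.integer(s$torsions$n)
  s[c("bonds", "angles", "torsions", "impropers", "charge", "sigma", "epsilon")]
}

union_adjacency <- function(b1, b2, n) {
  adj <- vector("list", n)
  add <- function(adj, i, j) {
    adj[[i + 1L]] <- union(adj[[i + 1L]], j)
    adj[[j + 1L]] <- union(adj[[j + 1L]], i)
    adj
  }
  for (b in list(b1, b2)) {
    if (nrow(b)) for (t in seq_len(nrow(b))) adj <- add(adj, b$i[t], b$j[t])
  }
  adj
}

derive_exclusions <- function(adj, n) {
  # graph distance 1 or 2 -> excluded; exactly 3 -> 1-4 scaled
  excl <- list(); p14 <- list()
  for (i in 0:(n - 1L)) {
    d1 <- adj[[i + 1L]]
    d2 <- setdiff(unique(unlist(lapply(d1, function(k) adj[[k + 1L]]))), c(i, d1))
    d3 <- setdiff(unique(unlist(lapply(d2, function(k) adj[[k + 1L]]))),
                  c(i, d1, d2))
    for (j in c(d1, d2)) if (j > i) excl[[length(excl) + 1L]] <- c(i, j)
    for (j in d3) if (j > i) p14[[length(p14) + 1L]] <- c(i, j)
  }
  to_df <- function(lst) {
    if (!length(lst)) return(data.frame(i = integer(), j = integer()))
    m <- do.call(rbind, lst)
    data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]))
  }
  list(excl = to_df(excl), p14 = to_df(p14))
}

#' EVB coupling parameters
#'
#' The constant gas-phase shift added to the product diabat and the constant
#' off-diagonal coupling element of the 2x2 EVB Hamiltonian. `H12` is stored
#' nonnegative; only its square enters the ground-state energy.
#'
#' @param delta_alpha Gas-phase shift (kcal/mol), added to the state-2 energy.
#' @param H12 Off-diagonal coupling (kcal/mol), must be >= 0.
#' @return Object of class `evb_coupling`.
#' @export
evb_coupling <- function(delta_alpha, H12) {
  stopifnot(is.finite(delta_alpha), is.finite(H12))
  if (H12 < 0) stop("H12 must be stored nonnegative (only H12^2 enters Eg)")
  structure(list(delta_alpha = as.numeric(delta_alpha), H12 = as.numeric(H12)),
            class = "evb_coupling")
}

#' Replace the coupling of an EVB system
#'
#' @param system An `evb_topology`, `evb_system` or `oracle_1d` object.
#' @param coupling An [evb_coupling()] object, or a calibration result from
#'   [calibrate_evb()].
#' @return The system with the new coupling installed.
#' @export
set_coupling <- function(system, coupling) {
  if (inherits(coupling, "calibration_result"))
    coupling <- evb_coupling(coupling$delta_alpha, coupling$H12)
  stopifnot(inherits(coupling, "evb_coupling"))
  if (inherits(system, "evb_system")) {
    system$topology$coupling <- coupling
  } else {
    system$coupling <- coupling
  }
  system
}

#' Morse bond energy
#'
#' V(r) = D * (1 - exp(-a * (r - r0)))^2: zero at the equilibrium length and
#' approaching the well depth D at dissociation.
#'
#' @param r Interatomic distance(s), Angstrom; must be positive.
#' @param bond List (or row) with elements `D` (kcal/mol), `a` (1/A),
#'   `r0` (A).
#' @return Energy in kcal/mol (vectorized over `r`).
#' @export
#' @examples
#' morse_energy(1.5, list(D = 100, a = 2, r0 = 1.5))  # 0 at the minimum
morse_energy <- function(r, bond) {
  if (any(!is.finite(r)) || any(r <= 0)) stop("distance r must be positive")
  stopifnot(bond$D > 0, bond$a > 0, bond$r0 > 0)
  bond$D * (1 - exp(-bond$a * (r - bond$r0)))^2
}

#' Diabatic energy with full per-term breakdown
#'
#' Evaluates one diabatic state of an EVB topology at the given coordinates.
#' Returns the six force-field terms (Morse bond, angle, torsion, improper,
#' electrostatic, van der Waals), each partitioned into reacting-reacting
#' (rr), reacting-surrounding (rs), and surrounding-surrounding (ss) groups.
#' Bonded terms whose atoms are all reacting count as rr; terms with no
#' reacting atom as ss; mixed terms as rs. Restraint energies are not part of
#' the breakdown (they are identical in both states and handled by the
#' sampler only).
#'
#' @param coords Numeric n_atoms x 3 matrix of coordinates (A).
#' @param topo An [evb_topology()].
#' @param state Which diabat, 1 (reactant-like) or 2 (product-like). Note the
#'   returned state-2 energy does not include the gas-phase shift
#'   `delta_alpha`; see [ground_state_energy()].
#' @return Object of class `energy_breakdown`: list with `terms` (3 x 6
#'   matrix, groups x terms) and `total`.
#' @export
diabatic_energy <- function(coords, topo, state = 1) {
  stopifnot(inherits(topo, "evb_topology"), state %in% c(1, 2))
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(topo$atoms) || ncol(coords) != 3)
    stop("coordinate count does not match atom count")
  res <- cpp_diabatic_energy(unclass_topology(topo), coords, as.integer(state))
  structure(list(terms = res$terms, total = res$total),
            class = "energy_breakdown")
}

#' Diabatic forces
#'
#' Analytic forces (negative gradient) of one diabatic state, used by the
#' sampler and testable against finite differences.
#'
#' @inheritParams diabatic_energy
#' @return n_atoms x 3 matrix of forces (kcal/mol/A).
#' @export
diabatic_forces <- function(coords, topo, state = 1) {
  stopifnot(inherits(topo, "evb_topology"), state %in% c(1, 2))
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(topo$atoms) || ncol(coords) != 3)
    stop("coordinate count does not match atom count")
  cpp_diabatic_forces(unclass_topology(topo), coords, as.integer(state))
}

# strip S3 classes so Rcpp sees plain lists/data.frames
unclass_topology <- function(topo) {
  list(atoms = topo$atoms,
       state1 = topo$state1, state2 = topo$state2,
       coupling = unclass(topo$coupling),
       restraint = topo$restraint, posres = topo$posres)
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("EVB diabatic energy breakdown (kcal/mol)\n")
  print(round(x$terms, 6))
  cat("total:", format(x$total), "\n")
  invisible(x)
}

#' Ground-state EVB energy and state weights
#'
#' Solves the 2x2 secular problem for the lower adiabatic surface:
#' Eg = (e1 + e2s)/2 - sqrt((e1 - e2s)^2 + 4 H12^2)/2, where e2s is the
#' state-2 energy already including the gas-phase shift. Also returns the
#' squared ground-eigenvector components w1, w2 (w1 + w2 = 1), used to mix
#' per-state energy components on the physical surface.
#'
#' @param eps1,eps2_shifted Diabatic energies (kcal/mol); `eps2_shifted`
#'   includes `delta_alpha`. Vectorized.
#' @param coupling An [evb_coupling()] (only `H12` is used here).
#' @return List with numeric vectors `Eg`, `w1`, `w2`.
#' @export
#' @examples
#' ground_state_energy(0, 0, evb_coupling(0, 86.8))$Eg  # -86.8
ground_state_energy <- function(eps1, eps2_shifted, coupling) {
  stopifnot(inherits(coupling, "evb_coupling"))
  if (any(!is.finite(eps1)) || any(!is.finite(eps2_shifted)))
    stop("diabatic energies must be finite")
  H <- coupling$H12
  d <- eps1 - eps2_shifted
  rad <- sqrt(d^2 + 4 * H^2)
  Eg <- 0.5 * (eps1 + eps2_shifted) - 0.5 * rad
  if (H == 0) {
    w1 <- as.numeric(eps1 <= eps2_shifted)
    w2 <- 1 - w1
  } else {
    t2 <- ((Eg - eps1) / H)^2
    w1 <- 1 / (1 + t2)
    w2 <- t2 / (1 + t2)
  }
  list(Eg = Eg, w1 = w1, w2 = w2)
}

#' Mapping potential
#'
#' The lambda-weighted linear mixture of the diabats used to drive sampling
#' from the reactant (lambda = 0) to the product (lambda = 1):
#' eps_m = (1 - lambda) * eps1 + lambda * eps2_shifted.
#'
#' @inheritParams ground_state_energy
#' @param lambda Mapping parameter in [0, 1].
#' @return Mapping energy (kcal/mol), vectorized.
#' @export
mapping_energy <- function(eps1, eps2_shifted, lambda) {
  if (any(lambda < 0) || any(lambda > 1)) stop("lambda must lie in [0, 1]")
  (1 - lambda) * eps1 + lambda * eps2_shifted
}

#' Energy-gap reaction coordinate
#'
#' The collective EVB reaction coordinate: the difference between the two
#' diabatic energies, antisymmetric under state exchange.
#'
#' @inheritParams ground_state_energy
#' @return eps1 - eps2_shifted (kcal/mol), vectorized.
#' @export
energy_gap <- function(eps1, eps2_shifted) {
  eps1 - eps2_shifted
}
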