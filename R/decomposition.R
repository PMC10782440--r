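#' Select reactant- and transition-state frame ensembles
#'
#' Pools frames from all windows and replicates and assigns them to the
#' reactant-state (RS) or transition-state (TS) ensemble when their energy
#' gap falls in the corresponding profile bin +/- `halfwidth` bins. Frames
#' carry both states' per-term breakdowns, the per-frame ground-state weights
#' (w1, w2), and coordinates when recorded.
#'
#' @param windows List of `evb_window` objects sampled with
#'   `record_breakdowns = TRUE`.
#' @param profile An `evb_profile` with bin edges (from
#'   [umbrella_profile()]).
#' @param halfwidth Bins on each side of the landmark bin to include
#'   (default 1; the means should be stable to widening, see the shipped
#'   stability checks).
#' @return List with elements `RS` and `TS`, each a `state_frames` object:
#'   list(breakdown1, breakdown2 (n x 18 matrices), w1, w2, de, coords
#'   (3*n_atoms x n or NULL), n).
#' @export
select_state_frames <- function(windows, profile, halfwidth = 1L) {
  windows <- as_window_list(windows)
  edges <- attr(profile, "edges")
  if (is.null(edges)) stop("profile carries no bin edges")
  lm <- find_landmarks(profile$dg)
  pick <- function(bin_idx) {
    lo <- edges[max(1L, bin_idx - halfwidth)]
    hi <- edges[min(length(edges), bin_idx + halfwidth + 1L)]
    gather_frames(windows, lo, hi)
  }
  rs <- pick(lm$rs)
  ts <- pick(lm$ts)
  if (ts$n == 0) stop_numerical("empty TS bin: no frames near the barrier top")
  if (rs$n < 20 || ts$n < 20)
    stop_numerical("fewer than 20 frames in an ensemble (RS %d, TS %d); run longer sampling",
                   rs$n, ts$n)
  list(RS = rs, TS = ts)
}

gather_frames <- function(windows, lo, hi) {
  b1 <- list(); b2 <- list(); w1 <- list(); w2 <- list(); de <- list()
  crd <- list()
  have_coords <- all(vapply(windows, function(w) !is.null(w$coords), logical(1)))
  for (w in windows) {
    if (is.null(w$breakdown1))
      stop("windows were sampled without breakdown recording")
    d <- w$frames$eps1 - w$frames$eps2s
    sel <- which(d >= lo & d < hi)
    if (!length(sel)) next
    b1[[length(b1) + 1L]] <- w$breakdown1[sel, , drop = FALSE]
    b2[[length(b2) + 1L]] <- w$breakdown2[sel, , drop = FALSE]
    cpl <- w$coupling %||% window_coupling(w)
    gw <- ground_state_energy(w$frames$eps1[sel], w$frames$eps2s[sel], cpl)
    w1[[length(w1) + 1L]] <- gw$w1
    w2[[length(w2) + 1L]] <- gw$w2
    de[[length(de) + 1L]] <- d[sel]
    if (have_coords) crd[[length(crd) + 1L]] <- w$coords[, sel, drop = FALSE]
  }
  n <- sum(vapply(de, length, integer(1)))
  structure(list(
    breakdown1 = if (n) do.call(rbind, b1) else NULL,
    breakdown2 = if (n) do.call(rbind, b2) else NULL,
    w1 = unlist(w1), w2 = unlist(w2), de = unlist(de),
    coords = if (have_coords && n) do.call(cbind, crd) else NULL,
    n = n), class = "state_frames")
}

# the coupling H12 is recoverable from stored frame energies:
# Eg = (e1+e2s)/2 - sqrt(de^2 + 4 H^2)/2
window_coupling <- function(w) {
  fr <- w$frames
  rad <- fr$eps1 + fr$eps2s - 2 * fr$Eg
  h2 <- (rad^2 - (fr$eps1 - fr$eps2s)^2) / 4
  evb_coupling(0, sqrt(max(0, stats::median(h2))))
}

#' Decompose the activation enthalpy into fragment energy terms
#'
#' Approximates the activation enthalpy by the difference of average
#' potential energies between the TS and RS ensembles, restricted to terms
#' involving the reacting fragment: interactions within the fragment (rr)
#' and between fragment and surroundings (rs). The surrounding-surrounding
#' term is deliberately never computed (it involves numerically very large
#' environment self-energies); no field for it exists. The
#' state-1/state-2 components of each frame are mixed with the ground-state
#' eigenvector weights (w1, w2), i.e. averages are taken on the physical
#' surface. The fragment total is further split into bonded (Morse bond,
#' angle, torsion, improper) and nonbonded (electrostatic, van der Waals)
#' contributions.
#'
#' @param rs_frames,ts_frames `state_frames` ensembles from
#'   [select_state_frames()].
#' @return Object of class `activation_decomposition`: `dU_rr`, `dU_rs`,
#'   `dU_tot_r` (= dU_rr + dU_rs), `dU_bonded`, `dU_nonbond`, and `terms`
#'   (named per-term deltas over rr+rs: bond, angle, torsion, improper,
#'   elec, vdw). dU_tot_r = dU_bonded + dU_nonbond holds exactly.
#' @export
decompose_activation <- function(rs_frames, ts_frames) {
  stopifnot(inherits(rs_frames, "state_frames"), inherits(ts_frames, "state_frames"))
  if (rs_frames$n == 0 || ts_frames$n == 0) stop("both ensembles must be nonempty")
  if (rs_frames$n < 20 || ts_frames$n < 20)
    warning("fewer than 20 frames in an ensemble; averages will be noisy")
  mixed_means <- function(fr) {
    mix <- fr$w1 * fr$breakdown1 + fr$w2 * fr$breakdown2
    colMeans(mix)
  }
  mts <- mixed_means(ts_frames)
  mrs <- mixed_means(rs_frames)
  d <- mts - mrs
  terms <- c("bond", "angle", "torsion", "improper", "elec", "vdw")
  rr <- d[paste0("rr_", terms)]
  rs <- d[paste0("rs_", terms)]
  activation_decomposition(stats::setNames(as.numeric(rr + rs), terms),
                           dU_rr = sum(rr), dU_rs = sum(rs),
                           per_group = list(rr = stats::setNames(as.numeric(rr), terms),
                                            rs = stats::setNames(as.numeric(rs), terms)))
}

#' Construct an activation-energy decomposition
#'
#' Builds the decomposition object from per-term TS-minus-RS deltas
#' (restricted to reacting-fragment terms). The aggregate fields satisfy
#' dU_tot_r = dU_bonded + dU_nonbond by construction, with
#' dU_bonded = bond + angle + torsion + improper and
#' dU_nonbond = elec + vdw.
#'
#' @param terms Named numeric vector with entries bond, angle, torsion,
#'   improper, elec, vdw (kcal/mol).
#' @param dU_rr,dU_rs Optional within-fragment and fragment-surroundings
#'   subtotals; default to the term sum and 0.
#' @param per_group Optional list with per-group term vectors.
#' @return Object of class `activation_decomposition`.
#' @export
#' @examples
#' d <- activation_decomposition(c(bond = 110, angle = 0, torsion = 0,
#'                                 improper = 0, elec = 1, vdw = 0))
#' d$dU_tot_r  # 111
activation_decomposition <- function(terms, dU_rr = sum(terms), dU_rs = 0,
                                     per_group = NULL) {
  need <- c("bond", "angle", "torsion", "improper", "elec", "vdw")
  stopifnot(all(need %in% names(terms)))
  terms <- terms[need]
  bonded <- sum(terms[c("bond", "angle", "torsion", "improper")])
  nonbond <- sum(terms[c("elec", "vdw")])
  structure(list(dU_rr = dU_rr, dU_rs = dU_rs,
                 dU_tot_r = bonded + nonbond,
                 dU_bonded = bonded, dU_nonbond = nonbond,
                 terms = terms, per_group = per_group),
            class = "activation_decomposition")
}

#' @export
print.activation_decomposition <- function(x, ...) {
  cat("Activation energy decomposition (TS - RS, kcal/mol)\n")
  cat(sprintf("  dU_tot_r  = %8.3f (rr %8.3f, rs %8.3f)\n",
              x$dU_tot_r, x$dU_rr, x$dU_rs))
  cat(sprintf("  dU_bonded = %8.3f, dU_nonbond = %8.3f\n",
              x$dU_bonded, x$dU_nonbond))
  print(round(x$terms, 3))
  invisible(x)
}

#' Measure geometric observables on stored frames
#'
#' Computes named interatomic distances and torsions (in degrees, wrapped to
#' (-180, 180]) per frame, e.g. the breaking and forming bond lengths and the
#' backbone torsions that characterize transition-state compactness.
#'
#' @param frames A `state_frames` object with coordinates (windows sampled
#'   with `record_coords = TRUE`), or a matrix of coordinates with
#'   3*n_atoms rows and one column per frame.
#' @param definitions List with elements `distances` (named list of atom id
#'   pairs, 0-based) and/or `torsions` (named list of atom id quadruples).
#' @return List with `series` (data.frame, one column per observable) and
#'   `means` (data.frame: name, type, mean, sem).
#' @export
measure_geometry <- function(frames, definitions) {
  crd <- if (inherits(frames, "state_frames")) frames$coords else frames
  if (is.null(crd)) stop("no coordinates recorded; sample with record_coords = TRUE")
  crd <- as.matrix(crd)
  natoms <- nrow(crd) / 3
  nfr <- ncol(crd)
  getxyz <- function(f, id) crd[(3 * id + 1):(3 * id + 3), f]
  check_ids <- function(ids, k) {
    if (length(ids) != k || any(ids < 0) || any(ids >= natoms) ||
        anyDuplicated(ids))
      stop("invalid atom id tuple: ", paste(ids, collapse = ","))
  }
  series <- list()
  meta <- list()
  for (nm in names(definitions$distances %||% list())) {
    ids <- definitions$distances[[nm]]
    check_ids(ids, 2)
    series[[nm]] <- vapply(seq_len(nfr), function(f)
      sqrt(sum((getxyz(f, ids[1]) - getxyz(f, ids[2]))^2)), numeric(1))
    meta[[nm]] <- "distance"
  }
  for (nm in names(definitions$torsions %||% list())) {
    ids <- definitions$torsions[[nm]]
    check_ids(ids, 4)
    series[[nm]] <- vapply(seq_len(nfr), function(f)
      dihedral_deg(getxyz(f, ids[1]), getxyz(f, ids[2]),
                   getxyz(f, ids[3]), getxyz(f, ids[4])), numeric(1))
    meta[[nm]] <- "torsion"
  }
  if (!length(series)) stop("no observables defined")
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  means <- data.frame(name = names(series),
                      type = unlist(meta[names(series)]),
                      mean = vapply(series, mean, numeric(1)),
                      sem = vapply(series, sem, numeric(1)),
                      row.names = NULL)
  list(series = as.data.frame(series), means = means)
}

# dihedral in degrees, (-180, 180]; errors on collinear backbone
dihedral_deg <- function(ri, rj, rk, rl) {
  b1 <- rj - ri; b2 <- rk - rj; b3 <- rl - rk
  n1 <- crossprod3(b1, b2)
  n2 <- crossprod3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-8 || sqrt(sum(n2^2)) < 1e-8)
    stop("torsion undefined: collinear atoms")
  m <- crossprod3(n1, n2)
  phi <- atan2(sum(m * b2) / sqrt(sum(b2^2)), sum(n1 * n2)) * 180 / pi
  if (phi <= -180) phi <- phi + 360
  phi
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
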