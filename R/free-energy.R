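#' Cumulative free energy along the mapping coordinate (FEP)
#'
#' Zwanzig exponential averaging between adjacent mapping windows:
#' dG(m -> m+1) = -kB T log < exp(-beta (eps_{m+1} - eps_m)) >_m, where the
#' perturbation is evaluated on stored per-frame diabatic energies. Forward
#' and backward estimates are averaged,
#' dG_m = (dG_fwd(m -> m+1) - dG_bwd(m+1 -> m)) / 2, and accumulated with
#' dG(lambda_1) = 0.
#'
#' @param windows A list of `evb_window` objects (one replicate) covering a
#'   ladder of lambda values at a common temperature.
#' @param temperature Temperature (K); defaults to the windows' common value.
#' @return Object of class `fep_result`: list with `lambda`, `dG_cum`,
#'   `dG_fwd`, `dG_bwd`, `temperature`.
#' @export
fep_cumulative <- function(windows, temperature = NULL) {
  windows <- as_window_list(windows)
  if (length(windows) < 2) stop("need at least two windows")
  temps <- vapply(windows, `[[`, numeric(1), "temperature")
  if (diff(range(temps)) > 1e-9) stop("windows must share one temperature")
  reps <- vapply(windows, `[[`, integer(1), "replicate")
  if (length(unique(reps)) > 1)
    stop("fep_cumulative expects a single replicate; loop over replicates")
  temperature <- temperature %||% temps[1]
  lam <- vapply(windows, `[[`, numeric(1), "lambda")
  ord <- order(lam)
  windows <- windows[ord]
  lam <- lam[ord]
  nf <- vapply(windows, function(w) nrow(w$frames), integer(1))
  if (any(nf < 10)) stop("window with fewer than 10 frames; refuse to estimate")
  beta <- 1 / (.KB * temperature)
  M <- length(windows)
  dG_fwd <- dG_bwd <- numeric(M - 1)
  for (m in seq_len(M - 1)) {
    dl <- lam[m + 1] - lam[m]
    fr <- windows[[m]]$frames
    du_f <- dl * (fr$eps2s - fr$eps1)
    dG_fwd[m] <- -logmeanexp(-beta * du_f) / beta
    frb <- windows[[m + 1]]$frames
    du_b <- -dl * (frb$eps2s - frb$eps1)
    dG_bwd[m] <- -logmeanexp(-beta * du_b) / beta
    for (du in list(du_f, du_b)) {
      w <- exp(-beta * (du - min(du)))
      ess <- sum(w)^2 / sum(w^2)
      if (ess < 0.05 * length(du))
        warning(sprintf("poor overlap between windows %d and %d (ESS %.1f of %d frames)",
                        m, m + 1, ess, length(du)))
    }
  }
  inc <- 0.5 * (dG_fwd - dG_bwd)
  structure(list(lambda = lam, dG_cum = c(0, cumsum(inc)),
                 dG_fwd = dG_fwd, dG_bwd = dG_bwd,
                 temperature = temperature),
            class = "fep_result")
}

as_window_list <- function(windows) {
  if (inherits(windows, "evb_window")) return(list(windows))
  stopifnot(is.list(windows), all(vapply(windows, inherits, logical(1), "evb_window")))
  windows
}

#' Free-energy profile along the energy gap (umbrella reweighting)
#'
#' Bins the energy gap de = eps1 - eps2s and reweights mapping-potential
#' samples onto the ground-state surface:
#' dg_m(de_n) = dG(lambda_m) - kB T log < 1[de in bin n] exp(-beta (Eg - eps_m)) >_m.
#' Per-bin values from all contributing windows are combined by a
#' count-weighted average, bins with fewer than `min_frames` total frames are
#' masked, unsampled edges are trimmed, and the profile is normalized so the
#' reactant-state minimum is zero.
#'
#' @param windows List of `evb_window` objects (any replicates; frames are
#'   pooled per window).
#' @param fep A [fep_cumulative()] result for the same lambda ladder. When
#'   windows from several replicates are pooled, pass the per-replicate FEP
#'   results as a list; the cumulative dG is averaged per lambda.
#' @param bins Either a single integer (number of equal bins over the sampled
#'   gap span; default 101) or a numeric vector of bin edges.
#' @param min_frames Bins with fewer pooled frames are masked.
#' @return Object of class `evb_profile`: data.frame with columns
#'   `de_center`, `dg`, `n_frames`, and attributes `edges`, `temperature`,
#'   `replicate`.
#' @export
umbrella_profile <- function(windows, fep, bins = 101L, min_frames = 10L) {
  windows <- as_window_list(windows)
  if (inherits(fep, "fep_result")) fep <- list(fep)
  stopifnot(all(vapply(fep, inherits, logical(1), "fep_result")))
  temperature <- fep[[1]]$temperature
  lam_ref <- fep[[1]]$lambda
  for (f in fep) stopifnot(max(abs(f$lambda - lam_ref)) < 1e-12)
  dG_tab <- rowMeans(matrix(vapply(fep, `[[`, numeric(length(lam_ref)),
                                   "dG_cum"), nrow = length(lam_ref)))
  beta <- 1 / (.KB * temperature)

  de_all <- unlist(lapply(windows, function(w) w$frames$eps1 - w$frames$eps2s))
  if (length(bins) == 1L) {
    # robust sampled span: extreme single-frame excursions would otherwise
    # stretch the grid into tail bins that never accumulate useful statistics
    span <- stats::quantile(de_all, c(5e-4, 1 - 5e-4), names = FALSE)
    edges <- seq(span[1], span[2], length.out = bins + 1L)
  } else {
    edges <- sort(as.numeric(bins))
  }
  nb <- length(edges) - 1L
  centers <- 0.5 * (edges[-1] + edges[-length(edges)])

  counts <- matrix(0, length(windows), nb)
  vals <- matrix(NA_real_, length(windows), nb)
  for (wi in seq_along(windows)) {
    w <- windows[[wi]]
    m <- which.min(abs(lam_ref - w$lambda))
    if (abs(lam_ref[m] - w$lambda) > 1e-9)
      stop("window lambda not found in FEP ladder")
    fr <- w$frames
    de <- fr$eps1 - fr$eps2s
    lw <- -beta * (fr$Eg - fr$eps_m)
    bin <- findInterval(de, edges, rightmost.closed = TRUE)
    keep <- bin >= 1 & bin <= nb
    bin <- bin[keep]; lwk <- lw[keep]
    if (!length(bin)) next
    Nm <- nrow(fr)
    for (b in unique(bin)) {
      sel <- lwk[bin == b]
      counts[wi, b] <- length(sel)
      # -kT log( (1/Nm) sum exp(lw) ), stable
      mx <- max(sel)
      vals[wi, b] <- dG_tab[m] - (mx + log(sum(exp(sel - mx))) - log(Nm)) / beta
    }
  }
  tot <- colSums(counts)
  dg <- rep(NA_real_, nb)
  for (b in which(tot >= min_frames)) {
    cw <- counts[, b]
    dg[b] <- sum(cw * vals[, b], na.rm = TRUE) / sum(cw)
  }
  ok <- which(!is.na(dg))
  if (!length(ok)) stop_numerical("no bin has enough frames")
  # contiguous sampled runs; a second substantially populated run separated
  # from the main one is a genuine sampling gap along the reaction coordinate
  run_id <- cumsum(c(1, diff(ok) > 1))
  runs <- split(ok, run_id)
  run_frames <- vapply(runs, function(r) sum(tot[r]), numeric(1))
  main <- runs[[which.max(run_frames)]]
  stray <- sum(run_frames) - max(run_frames)
  if (stray > 0.05 * sum(run_frames)) {
    lo <- max(main) + 1L
    stop_numerical("sampling gap between de = %.2f and the next sampled region; increase sampling or window count",
                   edges[min(lo, length(edges))])
  }
  span <- main
  prof <- free_energy_profile(centers[span], dg[span], tot[span],
                              temperature = temperature,
                              edges = edges[c(span, span[length(span)] + 1L)])
  normalize_profile(prof)
}

#' Construct a free-energy profile object
#'
#' Mostly internal; exported so that profiles can be built from external
#' per-bin values (e.g. re-read from disk) and fed to [extract_barriers()].
#'
#' @param de_center Bin centers along the energy gap (kcal/mol).
#' @param dg Free energy per bin (kcal/mol).
#' @param n_frames Frames per bin.
#' @param temperature Temperature (K).
#' @param edges Optional bin edges (length = bins + 1).
#' @param replicate Optional replicate id.
#' @return Object of class `evb_profile` (a data.frame).
#' @export
free_energy_profile <- function(de_center, dg, n_frames = Inf,
                                temperature = 298, edges = NULL,
                                replicate = NA_integer_) {
  stopifnot(length(de_center) == length(dg), !is.unsorted(de_center))
  df <- data.frame(de_center = de_center, dg = dg,
                   n_frames = rep_len(n_frames, length(dg)))
  structure(df, class = c("evb_profile", "data.frame"),
            temperature = temperature, edges = edges, replicate = replicate)
}

normalize_profile <- function(profile) {
  b <- tryCatch(find_landmarks(profile$dg), error = function(e) NULL)
  ref <- if (is.null(b)) min(profile$dg) else profile$dg[b$rs]
  profile$dg <- profile$dg - ref
  profile
}

# landmark finder: TS = interior maximum with the largest two-sided
# prominence; RS/PS = side minima; ties broken toward lower energy gap
find_landmarks <- function(dg) {
  n <- length(dg)
  if (n < 3) stop_numerical("profile needs at least 3 bins")
  best <- NULL
  for (t in 2:(n - 1)) {
    lmin <- min(dg[1:(t - 1)])
    rmin <- min(dg[(t + 1):n])
    if (dg[t] > lmin && dg[t] > rmin) {
      prom <- min(dg[t] - lmin, dg[t] - rmin)
      if (is.null(best) || prom > best$prom + 1e-12) {
        rs <- (1:(t - 1))[which.min(dg[1:(t - 1)])]
        ps <- ((t + 1):n)[which.min(dg[(t + 1):n])]
        best <- list(rs = rs, ts = t, ps = ps, prom = prom)
      }
    }
  }
  if (is.null(best)) stop_numerical("barrierless profile: no interior maximum")
  best
}

#' Extract activation and reaction free energies from a profile
#'
#' Identifies the reactant-state (RS), transition-state (TS) and
#' product-state (PS) bins of a gap-binned free-energy profile: the TS is the
#' interior maximum with the largest two-sided prominence, the RS and PS the
#' lowest bins on each side (RS on the low-gap side), ties broken toward
#' lower energy gap. Returns dG_act = dg(TS) - dg(RS) and
#' dG0 = dg(PS) - dg(RS).
#'
#' @param profile An `evb_profile`.
#' @return List of class `evb_barriers` with `dG_act`, `dG0`, and the bin
#'   indices `rs`, `ts`, `ps`.
#' @export
extract_barriers <- function(profile) {
  stopifnot(inherits(profile, "evb_profile"))
  lm <- find_landmarks(profile$dg)
  structure(list(dG_act = profile$dg[lm$ts] - profile$dg[lm$rs],
                 dG0 = profile$dg[lm$ps] - profile$dg[lm$rs],
                 rs = lm$rs, ts = lm$ts, ps = lm$ps),
            class = "evb_barriers")
}

#' @export
print.evb_barriers <- function(x, ...) {
  cat(sprintf("dG_act = %.3f kcal/mol, dG0 = %.3f kcal/mol (bins RS=%d TS=%d PS=%d)\n",
              x$dG_act, x$dG0, x$rs, x$ts, x$ps))
  invisible(x)
}

#' Per-replicate profiles and barrier statistics
#'
#' Splits a window set by replicate, computes one FEP + umbrella profile per
#' replicate on a common set of bin edges, and summarizes the activation and
#' reaction free energies as mean +/- SEM across replicates.
#'
#' @param windows An `evb_window_set` (or plain list of `evb_window`).
#' @param bins Bin count or explicit shared edges (see [umbrella_profile()]).
#' @param min_frames Passed to [umbrella_profile()].
#' @return List with `profiles` (per replicate), `per_replicate`
#'   (data.frame: replicate, dG_act, dG0), and `summary` (data.frame with
#'   mean and SEM for both quantities).
#' @export
replicate_barriers <- function(windows, bins = 101L, min_frames = 10L) {
  windows <- as_window_list(windows)
  reps <- vapply(windows, `[[`, integer(1), "replicate")
  ids <- sort(unique(reps))
  if (length(bins) == 1L) {
    de_all <- unlist(lapply(windows, function(w) w$frames$eps1 - w$frames$eps2s))
    span <- stats::quantile(de_all, c(5e-4, 1 - 5e-4), names = FALSE)
    bins <- seq(span[1], span[2], length.out = bins + 1L)
  }
  profiles <- list()
  tab <- data.frame(replicate = ids, dG_act = NA_real_, dG0 = NA_real_)
  for (k in seq_along(ids)) {
    wr <- windows[reps == ids[k]]
    fep <- fep_cumulative(wr)
    prof <- umbrella_profile(wr, fep, bins = bins, min_frames = min_frames)
    b <- extract_barriers(prof)
    profiles[[k]] <- prof
    tab$dG_act[k] <- b$dG_act
    tab$dG0[k] <- b$dG0
  }
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  list(profiles = profiles, per_replicate = tab,
       summary = data.frame(quantity = c("dG_act", "dG0"),
                            mean = c(mean(tab$dG_act), mean(tab$dG0)),
                            sem = c(sem(tab$dG_act), sem(tab$dG0))))
}
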