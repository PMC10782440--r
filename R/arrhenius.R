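#' Replicate activation free energies on a temperature ladder
#'
#' Container for per-temperature replicate values of the activation free
#' energy, the input to the Arrhenius-style decomposition into activation
#' enthalpy and entropy.
#'
#' @param data data.frame with columns `T` (K), `replicate`, `dG_act`
#'   (kcal/mol).
#' @param label System name.
#' @return Object of class `temperature_series` (a data.frame).
#' @export
temperature_series <- function(data, label = "system") {
  stopifnot(is.data.frame(data), all(c("T", "replicate", "dG_act") %in% names(data)))
  if (length(unique(data$T)) < 3)
    stop("need at least 3 distinct temperatures")
  if (any(!is.finite(data$dG_act))) stop("dG_act values must be finite")
  if (any(data$T <= 0)) stop("temperatures must be positive")
  structure(as.data.frame(data[c("T", "replicate", "dG_act")]),
            class = c("temperature_series", "data.frame"), label = label)
}

#' Activation enthalpy and entropy from an Arrhenius-style fit
#'
#' Ordinary least squares of y = mean dG_act(T) / T against x = 1 / T over
#' the per-temperature replicate means: the slope is the activation enthalpy
#' dH_act and the negative intercept the activation entropy dS_act, assuming
#' both are temperature-independent over the ladder span. Parameter standard
#' errors come from a seeded nonparametric bootstrap that resamples
#' replicates within each temperature.
#'
#' @param series A [temperature_series()].
#' @param ref_T Reference temperature (K) at which T*dS_act is reported.
#' @param n_boot Bootstrap resamples.
#' @param boot_seed Seed for the bootstrap stream.
#' @return Object of class `arrhenius_fit`: `dH_act` (kcal/mol), `dS_act`
#'   (kcal/mol/K), `TdS_at_ref` (kcal/mol), `ref_T`, standard errors
#'   `se_dH`, `se_dS`, `se_TdS`, `r_squared`, `per_T` (data.frame of
#'   per-temperature means), `label`.
#' @export
fit_arrhenius <- function(series, ref_T = 298, n_boot = 1000L,
                          boot_seed = 42L) {
  stopifnot(inherits(series, "temperature_series"))
  if (ref_T <= 0) stop("reference temperature must be positive")
  per_T <- stats::aggregate(dG_act ~ T, data = series, FUN = mean)
  per_T <- per_T[order(per_T$T), ]
  if (stats::var(1 / per_T$T) == 0) stop("zero variance in 1/T")
  fit1 <- function(tab) {
    fit <- stats::lm(I(dG_act / T) ~ I(1 / T), data = tab)
    cf <- stats::coef(fit)
    y <- tab$dG_act / tab$T
    ss_tot <- sum((y - mean(y))^2)
    # direct R^2 (summary.lm warns on exactly collinear, i.e. noiseless, data)
    r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
    c(dH = unname(cf[2]), dS = -unname(cf[1]), r2 = r2)
  }
  est <- fit1(per_T)
  boot <- matrix(NA_real_, n_boot, 2)
  groups <- split(series$dG_act, series$T)
  Ts <- as.numeric(names(groups))
  with_rng(boot_seed, {
    for (b in seq_len(n_boot)) {
      means <- vapply(groups, function(g) mean(sample(g, length(g), replace = TRUE)),
                      numeric(1))
      bt <- fit1(data.frame(T = Ts, dG_act = means))
      boot[b, ] <- bt[1:2]
    }
  })
  se <- apply(boot, 2, stats::sd)
  structure(list(dH_act = est[["dH"]], dS_act = est[["dS"]],
                 TdS_at_ref = ref_T * est[["dS"]], ref_T = ref_T,
                 se_dH = se[1], se_dS = se[2], se_TdS = ref_T * se[2],
                 r_squared = est[["r2"]], per_T = per_T,
                 label = attr(series, "label")),
            class = "arrhenius_fit")
}

#' Thermodynamic activation parameters at a temperature
#'
#' Evaluates the fitted linear model at temperature T through the Gibbs
#' relation dG_act(T) = dH_act - T * dS_act, and reports T * dS_act
#' alongside.
#'
#' @param fit An [fit_arrhenius()] result (or any list with `dH_act` and
#'   `dS_act`).
#' @param T Temperature (K), > 0.
#' @return List with `dG_act`, `dH_act`, `TdS` (kcal/mol).
#' @export
#' @examples
#' f <- structure(list(dH_act = 12.9, dS_act = -2.9 / 298), class = "arrhenius_fit")
#' thermo_at_temperature(f, 298)$dG_act  # 15.8
thermo_at_temperature <- function(fit, T) {
  if (T <= 0) stop("temperature must be positive")
  list(dG_act = fit$dH_act - T * fit$dS_act,
       dH_act = fit$dH_act,
       TdS = T * fit$dS_act)
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit [%s]: dH_act = %.3f +/- %.3f kcal/mol, T*dS_act(%g K) = %.3f +/- %.3f kcal/mol (R^2 = %.4f)\n",
              x$label %||% "system", x$dH_act, x$se_dH, x$ref_T,
              x$TdS_at_ref, x$se_TdS, x$r_squared))
  g <- thermo_at_temperature(x, x$ref_T)
  cat(sprintf("dG_act(%g K) = %.3f kcal/mol\n", x$ref_T, g$dG_act))
  invisible(x)
}

#' Arrhenius plot (dG_act/T against 1/T)
#'
#' @param x An `arrhenius_fit`.
#' @param ... Passed to [plot()].
#' @export
plot.arrhenius_fit <- function(x, ...) {
  invT <- 1 / x$per_T$T
  y <- x$per_T$dG_act / x$per_T$T
  plot(invT, y, xlab = "1/T (1/K)", ylab = "dG_act / T (kcal/mol/K)",
       main = sprintf("Arrhenius plot: %s", x$label %||% "system"), ...)
  graphics::abline(a = -x$dS_act, b = x$dH_act, col = "steelblue")
  invisible(x)
}
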