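---
title: "Methods: EVB free-energy profiles and activation thermodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EVB free-energy profiles and activation thermodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model, the numerical choices, and the synthetic
systems shipped with **evbthermo**, together with their limitations. Code
chunks are shown but not evaluated at build time; every number quoted below
is reproduced by the package test suite or by `scripts/acceptance.R`.

## 1. The two-state EVB model

A reaction is described by two diabatic states: state 1 (reactant bonding
pattern) and state 2 (product bonding pattern). Each state has its own
force field — Morse bonds, harmonic angles, periodic torsions, harmonic
impropers, Coulomb and Lennard-Jones nonbonded terms — evaluated in
kcal/mol with AKMA-style constants (`evb_constants()`). The ground-state
(adiabatic) energy is the lower eigenvalue of the 2x2 Hamiltonian

$$E_g = \tfrac12(\varepsilon_1 + \varepsilon_2') -
\tfrac12\sqrt{(\varepsilon_1-\varepsilon_2')^2 + 4H_{12}^2},
\qquad \varepsilon_2' = \varepsilon_2 + \Delta\alpha,$$

with two adjustable parameters: the gas-phase shift $\Delta\alpha$ and the
(constant) off-diagonal coupling $H_{12}$. The reaction coordinate is the
energy gap $\Delta\varepsilon = \varepsilon_1 - \varepsilon_2'$, and
sampling is driven by the mapping potential
$\varepsilon_m = (1-\lambda)\varepsilon_1 + \lambda\varepsilon_2'$ over 51
windows, $\lambda = 0, 0.02, \dots, 1$.

Nonbonded exclusions (1-2, 1-3) and scaled 1-4 pairs are derived from the
*union* bond graph of both states, so both diabats share one nonbonded
list and the gap stays smooth through the bonding change.

## 2. Sampling

Dynamics use the BAOAB splitting of Langevin dynamics, which samples the
canonical ensemble accurately at finite timestep — a requirement here,
because the free-energy estimators consume Boltzmann statistics directly.
Defaults (`simulation_config()`):

| parameter | default | rationale |
|---|---|---|
| timestep | 1 fs | stable for Morse bonds with D = 100, a = 2 |
| friction | 30 ps⁻¹ | moderately underdamped vs ~100 ps⁻¹ bond frequencies |
| equilibration | 6 stages, 1 K → target | gentle heat-up; last stage 5000 steps |
| production | 40 000 steps/window | see convergence study below |
| stride | 5 | decorrelates stored frames |

Equilibration is verified by the trailing-average kinetic temperature with
a degrees-of-freedom-aware allowance ($3\sigma$ of the expected
$\chi^2$ fluctuation); a single particle in a harmonic well at 298 K lands
in [268, 328] K. With friction set to zero the integrator conserves energy
to < 0.01 kcal/mol/ps at a 0.5 fs timestep. All random numbers come from a
per-window-seeded `mt19937_64` stream (window seed = master seed +
10000·replicate + window index), so every result is a pure function of the
master seed.

## 3. Free-energy estimators

Adjacent-window free energies use Zwanzig exponential averaging in both
directions, averaged,
$\Delta G_{m\to m+1} = \tfrac12(\Delta G^{fwd} - \Delta G^{bwd})$,
accumulated over $\lambda$ (`fep_cumulative()`). The profile along the gap
is obtained by umbrella reweighting each window to the ground surface
(`umbrella_profile()`):

$$\Delta g(\Delta\varepsilon_n) = \Delta G(\lambda_m) - k_BT \log
\left\langle \mathbf{1}[\Delta\varepsilon \in n]\,
e^{-\beta(E_g - \varepsilon_m)}\right\rangle_m,$$

combined across windows with frame-count weights over 101 bins. Landmarks
are found geometrically: the transition state is the interior maximum with
the largest two-sided prominence, the reactant/product states the flanking
minima, ties broken toward lower gap.

Numerical choices that matter:

* **Bin span.** The grid spans the (5e-4, 1 − 5e-4) quantiles of the pooled
  gap values, not the min/max: single-frame excursions otherwise create
  marginal wing bins whose statistical noise alone exceeds the 0.2 kcal/mol
  accuracy budget.
* **Starved bins.** Bins with fewer than 10 frames are masked; if masked
  interior runs exceed 5% of frames the profile aborts with a classed
  `evbthermo_numerical` error (a genuine sampling gap should fail loudly,
  not silently interpolate).
* **Production length.** On the calibrated 1D oracle the deviation between
  the sampled profile and exact quadrature fell from max 0.26 (8k steps)
  to 0.15 (20k) to at most 0.12 kcal/mol over seven seeds at 40k steps,
  which sets the default.

## 4. The 1D oracle

`make_oracle_1d("reference")` is a single particle on two harmonic diabats
(k = 300, minima at 0 and 1 Å). Because it is one-dimensional, the exact
profile follows from quadrature over the Boltzmann weight
(`oracle_profile_quadrature()`), giving a sampling-free reference for the
whole FEP/umbrella stack; the `"symmetric"` preset has $\Delta G_0 = 0$
exactly by symmetry.

```{r}
library(evbthermo)
sys <- make_oracle_1d("reference")
cal <- calibrate_evb(sys, calibration_targets(24.5, -12.8, 0.3, 298))
cal
sys <- set_coupling(sys, cal)
```

## 5. Calibration

`calibrate_evb()` fits $(\Delta\alpha, H_{12})$ to target activation and
reaction free energies by damped (0.7) secant/Broyden iteration on the
residual vector, exploiting the near-separation of effects ($\Delta\alpha$
shifts $\Delta G_0$ roughly 1:1; $H_{12}$ mainly lowers the barrier). Each
iterate is re-evaluated from scratch — exactly by quadrature for 1D
oracles (effective tolerance min(tol, 1e-3), since there is no noise to
hide behind), or by re-running the sampled protocol with fresh seeds (the
tolerance is then never tighter than twice the replicate SEM). Barrierless
iterates halve $H_{12}$ and retry; non-convergence raises an error that
carries the full iteration trace. On the reference oracle the fit
converges in 6 iterations to $\Delta\alpha = -12.861$, $H_{12} = 7.259$,
achieving (24.4995, −12.8005) against targets (24.5, −12.8). Ten
independent sampled replicates of the calibrated system then reproduce
both targets within 0.3 kcal/mol (24.48, −12.81 with master seed 1).

The default reaction free-energy target is −12.8 kcal/mol (experimental
solution value); a DFT estimate of −13.2 is an equally defensible input
and can be passed explicitly.

## 6. Activation enthalpy and entropy

`fit_arrhenius()` regresses the per-temperature means of
$\Delta G^\ddagger(T)/T$ on $1/T$ over a 288–313 K ladder (6 points):
slope = $\Delta H^\ddagger$, negative intercept = $\Delta S^\ddagger$,
assuming both are temperature-independent over the 25 K span. Standard
errors come from a seeded nonparametric bootstrap that resamples
replicates within each temperature (1000 resamples, fixed stream).
Noiseless synthetic ladders (`arrhenius_fixture()`) are recovered to
machine precision; a fully sampled ladder on the 1D oracle returns
$\Delta H^\ddagger = 24.65 \pm 0.15$ against a quadrature truth of 24.50
with $R^2 > 0.999$.

## 7. The 3D toy reaction and decomposition

`make_toy_reaction()` builds a desk-scale analog of a unimolecular
rearrangement: a nine-atom fragment (six-ring plus three-atom arm) in
which a state-1 Morse bond (ring→arm) breaks while a state-2 Morse bond
(arm→ring) forms, with state-dependent ±0.25 fragment charges — across
the breaking bond in state 1, across the rigid ring (the forming-bond
carbon and its para partner) in state 2 — plus a monoatomic LJ bath and a
flat-bottom spherical container.

Two design choices matter for the mechanics. First, the reactant is
*pre-organized*: the arm tip is built 2.7 Å from the attack site and the
torsion phases are aligned so that this near-attack conformation is a
torsional minimum. Without this the free-energy maximum along the gap is
a conformational-search bottleneck with almost no state-2 character
(eigenvector weight $w_2 \approx 0.02$), which no electrostatic
perturbation of state 2 can touch; with it, the transition state sits
near the diabatic crossing with mixed character ($w_2 \approx 0.15$).
Second, the state-2 charges live on *rigid ring atoms*, so the product
charge pattern has the same geometry in every ensemble and an external
field shifts $\varepsilon_2'$ nearly uniformly along the reaction.

The `catalyst = TRUE` variant adds two position-restrained fixed
charges — an anion beside the ring atom that carries the product-like
+0.25 charge, and a distant counter-cation — leaving the fragment force
field untouched and net charge conserved. Lowering the state-2 surface
lowers both the mixed transition state and the product, so the sampled
barrier drops and the fragment–surroundings electrostatic activation
term turns negative. The bath avoids the catalyst sites in both
variants, so a same-seed reference/catalyst pair shares identical
coordinates and differs only in the added charges.

`select_state_frames()` pools frames whose gap lies near the RS/TS
landmark bins; `decompose_activation()` averages the per-term energy
breakdowns on the ground surface (mixing the two states' terms with the
eigenvector weights $w_1, w_2$), restricted to reacting-fragment terms:
within-fragment (rr) and fragment–surroundings (rs). The
surroundings–surroundings self-energy is deliberately never reported. The
additive identity dU_tot_r = dU_bonded + dU_nonbond holds exactly by
construction.

With the frozen preset coupling ($\Delta\alpha = -10$, $H_{12} = 3$) the
catalyst variant shows both a lower sampled barrier and a more negative rs
electrostatic activation term than the same-seed reference — the
sign-level analog of electrostatic transition-state stabilization. In the
reference the rs electrostatic term is exactly zero (the bath is
uncharged), so the catalyst signal is unambiguous.

## 8. Generator realism and limitations

* The toys are *structural analogs*, not chemical models: energies and
  barriers are in a physically plausible range but are not chorismate
  energetics. Only the calibration targets tie the oracle systems to real
  reaction numbers.
* In the toy TS ensemble the forming bond contracts (≈2.6 → ≈2 Å) while
  the breaking bond is barely stretched — the toy's transition state is
  dominated by the approach coordinate, unlike a real chair-like
  transition state where both bonds are partial. The pre-organized
  near-attack reactant deliberately removes the conformational-search
  contribution to the barrier.
* $H_{12}$ is a constant, not distance-dependent; solvent is a neutral LJ
  bath, so there is no dielectric screening or reorganization in the
  reference toy — which is precisely why the fixed-charge catalyst variant
  produces a clean electrostatic signal.
* Enthalpy/entropy from the Arrhenius fit inherit the usual strong
  anticorrelation of slope/intercept estimates over a narrow 1/T range;
  the bootstrap SEs quantify but do not remove this.
* The decomposition is an average-potential-energy difference, not a free
  energy; it approximates $\Delta H^\ddagger$ only up to PV and
  ensemble-reorganization terms, mirroring the standard practice it
  reimplements.
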