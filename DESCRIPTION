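Package: evbthermo
Title: Empirical Valence Bond Free-Energy Profiles and Activation Thermodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-state empirical valence bond (EVB) simulations of
    chemical reactions at desk scale. Evaluates diabatic and ground-state
    energies with full bonded/nonbonded breakdowns, samples mapping potentials
    with Langevin (BAOAB) dynamics, computes free-energy profiles along the
    energy-gap reaction coordinate by free energy perturbation with umbrella
    reweighting, calibrates the EVB gas-phase shift and off-diagonal coupling
    against reference activation and reaction free energies, extracts
    activation enthalpies and entropies from Arrhenius-style regression of
    dG/T on 1/T, and decomposes the activation enthalpy into reacting-fragment
    bonded and nonbonded contributions. Ships analytically solvable
    one-dimensional oracle systems and three-dimensional toy reaction systems
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    bio3d,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
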