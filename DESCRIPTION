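Package: saftscreen
Title: PC-SAFT Phase Equilibria for Drug-Polymer Compatibility Screening
Version: 0.1.0
Authors@R:
    person("saftscreen", "developers", email = "saftscreen@example.org",
           role = c("aut", "cre"))
Description: A from-scratch implementation of the perturbed-chain statistical
    associating fluid theory (PC-SAFT) equation of state, including the
    hard-chain, dispersion and association contributions and the copolymer
    (heterosegmented chain) extension, together with the phase-equilibrium
    machinery needed for amorphous solid dispersion (ASD) screening:
    solid-liquid equilibrium solubility curves of crystalline drugs in
    amorphous polymers, liquid-liquid (amorphous-amorphous phase separation)
    binodal curves via an alternating-tangent construction, prediction-error
    statistics (AARD/ARD), polymer compatibility ranking with a demixing
    penalty, single-point binary interaction parameter fitting, and a
    simulated-annealing estimator of drug PC-SAFT parameters from solubility
    data in low-molar-mass solvents. Seeded generators provide synthetic
    sparse calorimetry-style solubility data so every pipeline stage is
    testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
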