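Package: nkrsig
Title: Spatial Stochastic Modeling of Activating and Inhibitory NK-Cell
    Receptor Cluster Signaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Spatially resolved kinetic Monte Carlo (spatial Gillespie)
    simulation of early-time signaling by the activating NKG2D and
    inhibitory KIR2DL1 Natural Killer cell receptors on a chambered
    membrane lattice, together with the analysis layers needed to study
    how the submicron cluster geometry of the two receptor types shapes
    ligand-dose discrimination: synthetic binary cluster-map generation
    emulating binarized superresolution images, disjoint/overlapping/
    homogeneous initial-configuration builders, a deterministic 14-state
    reference model of the activating module, two-point correlation
    analysis of binary maps, Gamma fits and Kullback-Leibler divergences
    of phospho-Vav1 response distributions, and mutual information and
    Blahut-Arimoto channel capacity of the dose-to-response channel.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    MASS,
    yaml,
    jsonlite,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
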