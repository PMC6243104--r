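Package: loopmsm
Title: Markov State Model Analysis of Protein Loop Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds Markov state models of protein loop conformational
    dynamics from molecular dynamics trajectory ensembles. Computes backbone
    phi/psi dihedral time series for a selected loop, estimates a time-lagged
    independent component analysis (tICA) decomposition, clusters the
    projected frames into microstates with k-medoids, estimates reversible
    maximum-likelihood transition matrices with implied-timescale lag
    selection, coarse-grains the microstate model into metastable macrostates
    with PCCA+, and characterizes each macrostate structurally (hydrogen-bond
    occupancy, Shrake-Rupley solvent-accessible surface area, centroid
    conformations, projection of external crystal conformations). Includes a
    hidden-Markov von Mises generator of synthetic dihedral trajectories so
    the whole pipeline is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
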