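Package: toccsl
Title: Single-Molecule Brightness Analysis of Membrane Protein Stoichiometry
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for determining the subunit stoichiometry of membrane
    proteins from single-molecule TIRF microscopy. Implements the TOCCSL
    (thinning out clusters while conserving stoichiometry of labeling)
    brightness analysis: conversion of raw camera frames to photon counts,
    detection and Gaussian fitting of diffraction-limited spots,
    estimation of the single-fluorophore brightness distribution,
    autoconvolution to higher-order brightness densities, and a
    simplex-constrained mixture fit yielding oligomer fractions with
    bootstrap uncertainties. Also fits FRAP recovery curves (one-phase
    association), models subunit exchange across repeated photobleaching
    runs, and ships a seeded synthetic-data generator emulating the full
    TIRF/TOCCSL experiment so that every analysis stage can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
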