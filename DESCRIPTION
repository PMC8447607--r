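Package: memshape
Title: Membrane Curvature, Vesiculation Kinetics and Conformational
    Ensembles from Coarse-Grained Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for coarse-grained membrane-remodeling
    simulations. Estimates signed membrane curvature of bicelle and
    vesicle shapes by least-squares sphere fitting, extracts waiting
    times for bicelle-to-vesicle transitions and fits a lagged
    single-Poisson (shifted-exponential) kinetic model to obtain
    vesiculation rates and acceleration factors, and computes
    protein conformational-ensemble statistics (radius-of-gyration
    densities, RMSF after Kabsch superposition, pairwise RMSD, and
    gromos clustering). Includes a synthetic-trajectory generator with
    known ground truth for end-to-end validation, readers and writers
    for multi-model PDB, GRO and XYZ coordinate files, and
    amphipathic-helix sequence descriptors (mean hydrophobicity,
    hydrophobic moment, net charge).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    seqinr,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
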