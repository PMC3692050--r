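Package: remfold
Title: Restraint-Guided Coarse-Grained Protein Folding with Replica-Exchange Monte Carlo
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for template-based and de novo protein structure
    modeling on a coarse-grained C-alpha trace. Generates consensus distance
    restraints from aligned structural templates (min/max or mean +/- sigma
    ranges gated on pairwise GDT_TS), samples conformations with a
    replica-exchange Metropolis Monte Carlo engine under a surrogate
    coarse-grained energy with flat-bottom restraint penalties, and selects
    models by K-means clustering of trajectory snapshots with density-ranked
    medoid/average representatives. Includes Kabsch superposition, GDT_TS,
    radius of gyration and end-to-end observables, PDB C-alpha I/O, a
    restraint-edit directive language, and a synthetic fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
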