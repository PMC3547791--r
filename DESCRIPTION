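Package: RepeatPull
Title: Mechanical Unfolding Analysis for Steered Pulling of Repeat Proteins
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse constant-velocity steered pulling of tandem
    repeat proteins such as the seven-ankyrin-repeat protein Gankyrin, alone
    or bound to a ligand. Provides the transferred-work integral and its
    exact per-repeat decomposition from telescoping anchor positions,
    force-peak identification from the Gaussian body of the force
    distribution, worm-like chain contour-length fits at fixed persistence
    length with contour-length-increment periodicity analysis, per-repeat
    RMSD unfolding midpoints with order-of-unfolding contingency statistics
    and an exact Fisher r x c test, and native-contact and ligand-binding
    lifetime maps. A seeded Bell-kinetics worm-like chain pulling simulator
    generates force traces and coordinate trajectories with full ground
    truth, so every analysis stage can be validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    bio3d,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'trajio.R'
    'wlc.R'
    'synthetic.R'
    'forcePeaks.R'
    'work.R'
    'unfolding.R'
    'contacts.R'
    'pipeline.R'
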