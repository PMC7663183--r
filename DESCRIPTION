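Package: fabqsar
Title: QSAR Modelling of Antibody Fab Hydrophobicity from Sequence and Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end quantitative structure-activity relationship (QSAR)
    workflow for predicting hydrophobic interaction chromatography (HIC)
    retention times of monoclonal antibody Fab regions. Annotates heavy and
    kappa light chains into the 28 IMGT substructures (CDRs, framework
    regions and constant-domain strands), generates descriptor tables from
    primary sequence (amino-acid scale sums and pepstats-like properties)
    and from all-atom structures (Shrake-Rupley solvent accessible surface
    area, relative solvent accessibility and hydropathy-weighted surface
    properties), analyses multi-frame trajectories (RMSD, RMSF, essential
    motions, CDR SASA time series), and fits epsilon-support-vector
    regression models with Kennard-Stone splitting, V-WSP collinearity
    reduction, consensus GA-PLS descriptor selection, repeated k-fold grid
    search and full validation diagnostics (Y-randomisation, learning
    curves, prediction intervals, hierarchical clustering and PCA).
    Includes seeded synthetic-fixture generators for every input type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    bio3d,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
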