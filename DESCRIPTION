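Package: vsfuse
Title: Ligand-Based Virtual Screening with Fingerprint Data Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native toolkit for ligand-based virtual screening.
    Reads compound libraries (SMILES/SDF), applies drug-likeness and
    reactive-group prefilters, computes four 2D molecular fingerprints
    (166-key MACCS structural keys, radial/circular, dendritic path-tree,
    and MOLPRINT2D atom-environment fingerprints), ranks libraries by
    Tanimoto similarity with MAX/SUM similarity and group data fusion,
    and scores rankings with early-enrichment metrics (enrichment factor,
    sensitivity/specificity, ROC/AUC, BEDROC). Also includes hierarchical
    clustering of actives, property-matched decoy generation, a simplified
    3D pharmacophore screen over conformer ensembles, and a seeded
    synthetic benchmark generator so the whole funnel can be exercised
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    ChemmineR,
    ChemmineOB,
    bio3d,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
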