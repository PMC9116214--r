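Package: sfct
Title: Scoring-Function Correction Terms for Protein-Ligand Docking Rescoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and applies a machine-learned scoring-function correction
    term for protein-ligand docking. Poses are featurized as multi-shell
    residue-class by ligand-element contact counts, a boosted random-forest
    regressor predicts each pose's heavy-atom RMSD from the native pose, and
    the predicted RMSD is linearly combined with any docking score to improve
    pose ranking, virtual screening enrichment, and reverse (target-fishing)
    screening. Includes symmetry-corrected ligand RMSD, screening metrics
    (enrichment factor, ROC-AUC, docking success rates), readers for PDB,
    PDBQT, SDF and MOL2 pose files, and a fully self-contained synthetic
    decoy-pose generator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    ranger,
    igraph,
    bio3d,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    pROC,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
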