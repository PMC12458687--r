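Package: liposcan
Title: Alpha-Sphere Pocket Detection and Lipid-Binding Pocket
    Classification for Protein Structures
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects candidate ligand-binding pockets in protein
    structures as clusters of alpha spheres (empty circumspheres tangent
    to four atoms), describes each pocket with seventeen physicochemical
    descriptors (volume, surface areas, hydrophobicity and polarity
    scores, sphere density and extent, flexibility), labels pockets
    against bound ligands to curate lipid-binding (LBP), non-lipid
    (nLBP), pseudo (PP) and heme pocket corpora, trains and evaluates an
    ensemble classifier for lipid-binding pockets under class imbalance,
    and scans proteomes of predicted structure models (pLDDT-filtered,
    signal-peptide trimmed) to rank putative lipid-binding proteins by
    their best pocket score. Includes a synthetic-fixture generator for
    engineered cavities and class-conditional descriptor tables so the
    full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    ranger,
    e1071,
    rpart,
    class,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    randomForest,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: StructuralBioinformatics, Classification, Proteomics
RoxygenNote: 7.3.3
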