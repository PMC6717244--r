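Package: xtalface
Title: Classification of Biological and Crystal-Packing Protein Interfaces
    Using Covariation Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Distinguishes biological protein-protein interfaces from
    crystal-packing contacts in X-ray structures by combining classical
    geometric and compositional interface descriptors with covariation
    signals extracted from deep multiple sequence alignments.  Provides
    Shrake-Rupley solvent accessible surface area, interface detection
    with core/rim assignment, crystal symmetry-mate reconstruction, an
    APC-corrected inverse-covariance coupling scorer with adapters for
    PSICOV and CCMpred output, a 69-component interface feature vector,
    F-score feature selection with random-forest and RBF-SVM
    classifiers under leakage-free cross-validation, and a synthetic
    test bed of toy complexes and coupling-planted alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    bio3d,
    e1071,
    jsonlite,
    randomForest,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
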