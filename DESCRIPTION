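Package: lipidGGM
Title: Lipid Class Prediction from Gaussian Graphical Models of LC-MS
    Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts LIPID MAPS lipid classes for untargeted LC-MS MS1
    features by combining accurate-mass database matching with a Gaussian
    graphical model (GGM) estimated from feature intensities. Edges of the
    GGM are partial correlations retained by an empirical-Bayes
    multiple-testing procedure; lipid subclass scores propagate database
    matches of one- and two-hop network neighbours within a retention-time
    window, with a self-match weight. Includes neighbourhood-diversity and
    score-margin quality scores, a closest-m/z baseline with randomized tie
    resolution, hierarchical evaluation utilities, a permutation-based
    lipid-class enrichment analysis (empirical Fisher's method), ranked-list
    concordance via rolling Jaccard curves, and a synthetic-data generator
    emulating block-correlated class structure, adduct multiplicity and
    class-specific retention windows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
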