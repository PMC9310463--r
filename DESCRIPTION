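Package: ZetaScreen
Title: Zeta Statistics for Two-Dimensional High-Throughput Screens and
    Single-Cell Quality Control
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores perturbation-by-readout screens (RNAi/CRISPR pools
    against hundreds of functional readouts) with the zeta area statistic:
    readouts are Z-scored against negative controls, per-perturbation
    survival curves are built over a grid of Z cutoffs, and the area above
    an SVM decision boundary separating positive from negative control
    curves gives each gene a (optionally Z-weighted) zeta score. Hits are
    selected on the Screen Strength curve (1 - aFDR/bFDR against
    non-expressor internal negatives) via balance points or empirical
    false-positive levels. Includes siRNA off-target flagging by guide
    complementarity plus response correlation, consensus-clustered gene
    networks, a per-cell zeta score for droplet single-cell RNA-seq QC,
    multiple-testing baselines (Bonferroni, Gumbel extreme-value), and a
    synthetic-data generator so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    e1071,
    igraph,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Software, CellBasedAssays, QualityControl, SingleCell,
    Network, StatisticalMethod
RoxygenNote: 7.3.3
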