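Package: pathwayPower
Title: Power and Error Assessment for Pathway Differential-Expression Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and resampling framework for assessing pathway-level
    differential-expression tests. Implements three pathway statistics (GSEA
    enrichment score, Hotelling's T-squared with an analytic shrinkage
    precision estimate, and the sum-of-t-square statistic) with permutation
    nulls; four simulation types producing uncorrelated, factor-correlated
    and gene-network-constrained correlated expression data, the latter via
    Gaussian graphical model covariance construction (pairwise iterative
    proportional scaling and alternating projection); harnesses estimating
    statistical power, false-positive rate and significant-pathway counts
    with bootstrap error bars; and a bootstrap surrogate-data pipeline for
    labeled expression matrices, including optimal-sample-size regression,
    pathway correlation profiling and detection-call distribution estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    fgsea,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
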