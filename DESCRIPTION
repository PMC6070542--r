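Package: connrep
Title: Test-Retest Reproducibility of Structural Brain Connectivity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying short-term test-retest reproducibility of
    weighted structural brain networks built from probabilistic-tractography
    connectivity matrices. Implements group-level connectivity thresholding
    under common (pooled-session) and separate (per-session) strategies,
    weighted network metrics (global and local efficiency, clustering
    coefficient, characteristic path length) with cost normalization,
    sparsity-integrated metric summaries, and edge-wise and metric-wise
    reproducibility statistics: within- and between-subject coefficients of
    variation, two-way absolute-agreement single-measures intraclass
    correlation ICC(A,1), and Pearson similarity. A synthetic test-retest
    cohort generator with a known variance-components structure provides
    ground truth for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    pracma,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
LinkingTo:
    Rcpp
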