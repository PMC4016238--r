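Package: foldthresh
Title: Fold-Change-Threshold Differential Expression Tests for Digital
    Count Data
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Differential-expression analysis of NanoString-style digital
    gene-expression counts relative to a fold-change threshold. Implements
    three-step normalization (positive-control scaling, reference-gene
    scaling, negative-control background correction), gene-wise linear
    models with classical and empirical-Bayes moderated t-statistics,
    composite-null threshold tests (TREAT on the moderated t, tTREAT on
    the classical t, and the two-stage stop-or-go design tTREAT2), a
    running fold-change model that derives expression-level-dependent
    thresholds from a limit-fold-change curve, a simulation engine for
    two-group digital-count experiments built on an inverse-gamma variance
    hierarchy, and evaluation utilities (false discoveries, missed genes,
    rank-based AUC with prediction intervals) for comparing the tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), limma, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
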