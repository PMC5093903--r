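Package: spatempo
Title: Spatio-Temporal Differential Expression Analysis of Sorted Cell Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential-expression analysis of bulk RNA-seq time courses from
    two FACS-sorted cell populations, modelled on the postnatal development of
    the mouse mammary epithelium (luminal and basal cells across eight time
    points). Provides counts-per-million normalisation and low-expression
    filtering, PCA-based quality control with covariate-to-principal-component
    association and correlation-based outlier detection, an ANOVA expression
    filter, per-time-point spatial and per-time-point-pair temporal
    differential-expression calls with fold-change and Benjamini-Hochberg FDR
    thresholds, classification of genes into luminal-specific, basal-specific
    and switching categories, all-pairwise time-point- and stage-specific gene
    calling, hypergeometric gene-set enrichment against GMT collections, and a
    negative-binomial count simulator with planted per-gene ground truth for
    calibration and parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
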