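Package: pscpipe
Title: Multiomics Analysis Pipeline for Pulmonary Sarcomatoid Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable re-implementation of a multiomics analysis
    workflow for pulmonary sarcomatoid carcinoma (PSC): consensus somatic
    mutation filtering across three variant callers with strand-aware F1/F2
    filter rules and tumor mutational burden, canonical cancer-gene (driver)
    curation with mutual-exclusivity and outcome tests, desk-scale clonal
    evolution reconstruction from cancer cell fractions (mixture clustering,
    constraint-based clonal trees, branched/linear classification, trunk
    mapping, purity estimation), transcriptomic immune subtyping (TMM
    normalization, consensus NMF with cophenetic rank selection, SAM gene
    ranking, Fisher-exact differential expression, single-sample gene-set
    immune/stromal scoring, nearest-centroid projection onto external
    cohorts), and subtype-survival association (Kaplan-Meier, log-rank,
    Cox proportional hazards). A synthetic-data module generates complete
    cohorts (caller VCFs, annotations, counts, clinical tables) with known
    ground truth so every stage is testable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    edgeR,
    survival,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
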