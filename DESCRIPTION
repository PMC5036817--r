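Package: qpcrStability
Title: Reference-Gene Stability Evaluation for RT-qPCR Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for selecting stable reference genes from replicate-level
    RT-qPCR quantification-cycle (Cq) panels. Implements replicate
    aggregation and the missing-amplification exclusion rule, four
    stability algorithms (geNorm M-value with iterative elimination and
    the Vn/n+1 pairwise-variation curve, NormFinder model-based
    inter/intragroup stability, BestKeeper descriptive statistics and the
    comparative delta-Ct method), geometric-mean rank aggregation across
    algorithms with cross-cohort consensus sets, and downstream
    re-normalization (relative quantities, normalization factors,
    normalized relative quantities) with non-parametric group comparison.
    Includes a seeded synthetic Cq-panel generator, with dropout, for
    validating every stage without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
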