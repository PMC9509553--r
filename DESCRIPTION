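Package: tnfomics
Title: Longitudinal Blood Multi-Omics Analysis of Anti-TNF Therapy Response
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis workflow for longitudinal whole-blood transcriptomic and
    DNA-methylation profiling of inflammatory bowel disease patients starting
    anti-TNF therapy. Implements median-of-ratios normalization, pairwise and
    impulse-model longitudinal differential expression, signed weighted
    co-expression networks with permutation Z-summary module preservation
    contrasted between clinical-outcome groups, combined-rank differential
    methylation, cis CpG-gene integration with permutation FDR, and
    random-forest prediction of remission with cross-validated AUC. Includes a
    longitudinal two-omics cohort simulator with planted ground truth and
    recovery scoring.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
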