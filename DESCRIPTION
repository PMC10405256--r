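Package: lineagedep
Title: Lineage Dependency, Resistance and Chromatin Identity Analysis for
    CRISPR Fitness Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores lineage-specific transcription-factor dependencies in
    CRISPR-Cas9 gene-effect (CERES) matrices, applies a three-stage filter
    cascade to define per-lineage core regulatory circuitries, classifies
    cell lines as lineage-factor sensitive or resistant, and detects
    acquired dependencies between the two groups with a permutation-based
    Cohen's D false-discovery-rate estimator. Also implements the
    accompanying chromatin-identity machinery: summit-centred
    significance-ranked consensus peak construction from narrowPeak calls,
    extended-read counting, differential-accessibility thresholding,
    window-based hypergeometric coupling of accessibility and expression
    changes, greedy Pearson-correlation clustering of binary open-chromatin
    profiles, cluster-specific region derivation, and summit-window overlap
    enrichment. A synthetic-data module generates every input with planted
    ground truth so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
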