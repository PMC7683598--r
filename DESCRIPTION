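Package: coregscan
Title: Family-Wide Alteration Testing for Transcription Factors and
    Coregulators in Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether whole classes of transcription factors and
    transcriptional coregulators (coactivators, corepressors, mixed-function
    coregulators) are altered more than expected by chance in tumor cohorts.
    Provides mutually exclusive gene-class catalog construction, tumor-normal
    and median-centered expression Z-scores, GISTIC-coded copy-number calls,
    gene-length-normalized mutation burden, random-set resampling tests with
    empirical p-values and FDR correction, frequent-alteration filtering with
    tumor clustering and cross-cohort intersection, quartile-stratified
    Kaplan-Meier survival screening, and a cis-regulation cascade linking
    ChIP-Seq peaks to genes through chromatin states and differential
    expression. A synthetic multi-omic cohort generator with planted effects
    makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
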