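Package: ampliqc
Title: Quality Control, Simulation and Variant Triage for Targeted
    Amplicon Sequencing of Degraded Samples
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end decision workflow for targeted amplicon panel
    sequencing of critical lung-cancer samples (formalin-fixed
    paraffin-embedded tissue, snap-frozen tissue, and circulating free
    DNA). Implements pre-analytic degradation scoring from multiplex-PCR
    yield ratios (Average Yield Ratio), qPCR-based quantification with a
    standard curve, sample routing to library protocols, a pileup-level
    simulator of amplicon coverage with degradation-linked dropout and
    whole-genome-amplification homopolymer insertion artifacts, two
    desk-scale variant callers (frequency-threshold and exact-binomial),
    a consensus triage cascade with limit-of-detection, coverage and
    artifact filters, per-amplicon coverage and uniformity metrics, and
    assay performance evaluation with Wilson score confidence intervals
    and dilution-series limit-of-detection determination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    rlang,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
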