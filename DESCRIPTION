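Package: cryptsplice
Title: Detection of Mutant-SF3B1-Like Cryptic 3' Splice Site Patterns from
    Junction Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect and characterise the aberrant 3' splice-site
    usage pattern induced by SF3B1 hotspot mutations and SUGP1 alterations
    from splice-junction count tables. Provides junction annotation and
    pairing against an exon model, junction-level splicing-index (SI)
    statistics with expression-quantile gating, mismatch-tolerant
    probe-burden screening of raw reads with coverage adjustment, PCA-based
    phenotype calling with a robust median + k*MAD cutoff, Fisher
    genotype-phenotype enrichment, and a supervised-PCA protocol for testing
    whether two alteration groups share a splice-aberration pattern relative
    to controls. A self-contained synthetic-data generator emulates cohorts
    with planted cryptic 3' acceptors so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
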