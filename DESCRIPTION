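Package: lrescan
Title: Discovery of RNA Hairpin Response Elements in UTRs and Downstream
    Validation Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scans 5' and 3' untranslated regions (UTRs) for tri-loop RNA
    stem-loop motifs of the kind bound by TRIM-NHL RNA-binding proteins
    (LIN-41 Response Elements, LREs), scores and categorizes candidate
    sites with a configurable position-weight model, aggregates per-mRNA
    predicted binding scores, and filters RIP-seq-enriched,
    germline-expressed transcripts into a candidate target table. Also
    provides the validation statistics used in such studies: 2^-ddCq qPCR
    fold changes, standard-curve quantification, condition ratios,
    hypergeometric gene-set overlap, exact rank-sum tests, and
    reporter-fluorescence ratio normalization, plus a synthetic-data
    generator that plants motifs with known truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
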