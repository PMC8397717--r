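Package: umitrial
Title: UMI Consensus ctDNA Quantification and Exact Phase II Trial
    Statistics for Uveal Melanoma Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for single-arm phase II studies of
    metastatic uveal melanoma that monitor treatment with hotspot-targeted
    circulating tumor DNA (ctDNA) sequencing. Converts hairpin-barcoded
    amplicon reads (SiMSen-Seq style libraries) into error-corrected read
    families and per-target variant allele frequencies using family-size
    dependent consensus thresholds; builds 96-channel single-base
    substitution catalogs and refits predefined mutational signatures by
    nonnegative least squares to flag UV-damaged genomes; performs the
    exhaustive search for Simon's optimal two-stage design together with
    exact binomial confidence intervals, response summaries and Fisher's
    exact test; and stratifies Kaplan-Meier survival by ctDNA, LDH, driver
    gene and BAP1/UV biomarkers with log-rank tests. Seeded synthetic-data
    generators emulate every input so the whole pipeline is testable
    without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    S4Vectors,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
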