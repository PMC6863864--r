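Package: foodauth
Title: Food Ingredient Authentication from Shotgun Sequencing Alignment Hits
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Turns taxonomically labelled paired-end alignment hits into
    species-level relative proportions for food ingredient authentication.
    Implements an alignment-hit filtering cascade (identity/coverage/e-value
    thresholds, per-mate best-bitscore retention, promiscuous-taxon removal,
    concordant-pair filtering), lowest-common-ancestor read assignment on an
    NCBI-style taxonomy, projection of internal-node read counts onto species
    leaves, a hypergeometric limit-of-detection model for choosing read
    subsample sizes, accuracy statistics for comparing observed and expected
    compositions, and a synthetic-data module (toy taxonomies, error-bearing
    paired reads, labelled hit tables with a cross-species confusion model,
    seeded FASTQ subsampling) so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
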