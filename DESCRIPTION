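Package: barcodeAudit
Title: Auditing Biodiversity Inventories with Two-Locus DNA Barcodes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for auditing field-based species inventories against DNA
    barcode evidence. Implements multi-method OTU delimitation from aligned
    COI barcodes (fixed-threshold single-linkage clustering as a BIN proxy,
    and automatic barcode gap discovery over a grid of prior intraspecific
    divergences), rule-based reconciliation of COI partitions with 16S
    clusters and collection localities into named species-level units,
    concordance scoring of field identifications against barcode OTUs, and
    incidence-based species richness comparison via sample-based rarefaction
    and the Chao2 estimator with 84% confidence intervals. A synthetic
    community generator with a configurable field-labelling error process
    supports end-to-end validation with known species truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Biostrings,
    ape,
    phangorn,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    knitr,
    rmarkdown
biocViews: Phylogenetics, Classification, SequenceMatching
Config/testthat/edition: 3
RoxygenNote: 7.3.3
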