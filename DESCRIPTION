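Package: mslevo
Title: Comparative Evolution of MSL Dosage-Compensation-Complex Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of MSL (male-specific lethal)
    dosage-compensation-complex binding sites between two Drosophila species:
    cross-species binding-site turnover and conservation calling through a
    one-to-one ortholog block map, classification of MOF/MSL1 sites into
    dosage-compensation (DC) and non-DC sites, an extended McDonald-Kreitman
    framework estimating the fraction of adaptive fixations (alpha) with
    four-fold degenerate sites as the neutral control, cleaning of repeat
    annotations and transposable-element family enrichment by log2 odds ratio,
    overlap of binding sites with cis-regulatory elements, and between-species
    expression divergence as one minus Spearman's rank correlation with
    bootstrap resampling. A synthetic-data generator emulates every input
    with known ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
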