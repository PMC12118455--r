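Package: metameth
Title: Bacterial 6mA Meta-Epigenomics from Nanopore-Style Raw Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for studying N6-methyladenine (6mA)
    methylomes of gut bacteria from nanopore-style raw current signals.
    Simulates squiggles over microbial genomes with motif-driven 6mA ground
    truth, segments and aligns raw samples to the reference, trains a small
    neural-network 6mA caller, aggregates per-read calls into per-site
    frequencies with depth/breadth genome filters, computes IUPAC motif
    modification ratios and 5-mer methylation-usage profiles, and provides
    the methDiff statistical framework (Bray-Curtis distances, principal
    coordinates, PERMANOVA, rank and t tests) together with prophage motif
    depletion and CDS/expression context analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
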