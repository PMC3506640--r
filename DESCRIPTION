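Package: barcodegap
Title: Barcode-Gap Evaluation and De Novo OTU Assembly Assessment for
    Bacterial Marker Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Evaluates candidate DNA barcodes for Bacteria and the de novo
    assembly of barcode amplicons into operational taxonomic units (OTUs).
    Delineates barcode regions from degenerate PCR primer pairs (16S rRNA
    variable regions and the cpn60 universal target), computes F84, K2P and
    JC pairwise distances with intra-/inter-specific partitioning and the
    median-based barcode-gap statistic, profiles nearest-neighbour percent
    identity in sliding windows along a target, simulates synthetic template
    panels, amplicon read sets and annotated genome fixtures, assembles reads
    with a greedy overlap-consensus assembler parameterized by minimum
    overlap length and identity, and scores assemblies with per-OTU
    sensitivity, specificity and residual error, including post-assembly
    primer trimming, 100% clustering and chimera flagging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
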