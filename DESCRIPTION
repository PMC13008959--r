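Package: circstress
Title: Characterization of a Plant circRNAome Under Abiotic Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end characterization of a circular RNA (circRNA) landscape
    from back-splice junction (BSJ) candidate tables: reliability-score
    filtering with intragenic/intergenic stratification, structural
    classification of circRNAs (multi-exonic, single-exonic, intronic),
    biogenesis feature statistics (flanking-intron lengths, host-gene
    exon/isoform propensity, inverted complementary sequence detection,
    repeat-density proxy), cross-species splice-site conservation
    classification, circRNA-host expression decoupling with a self-contained
    exact differential-expression test, ceRNA (miRNA sponge) network
    construction with a plant-style target scorer, and chloroplast locus
    clustering enrichment. Ships a fully parameterized synthetic-data
    generator with planted ground truth so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
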