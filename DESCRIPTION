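Package: NPCLtools
Title: Discovery and Evaluation of Universal Nuclear Protein-Coding Locus Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for developing universal nuclear
    protein-coding locus (NPCL) markers from annotated genomes: mining of
    long single-copy exons, cross-genome orthology screening with an
    internal seeded local aligner, constraint-based PCR primer-pair design
    with a cross-genome conservation score, cytochrome-b-calibrated
    substitution-rate estimation with site-bootstrap standard errors,
    supermatrix concatenation with neighbor-joining trees and bootstrap
    support, PCR validation-matrix summaries, and intraspecific
    polymorphism and neutrality statistics (segregating sites, haplotype
    and nucleotide diversity, Tajima's D, multilocus HKA). Includes a
    genome-pair simulator with planted orthologs, paralogs and deletions,
    and an infinite-sites coalescent sampler, so every stage is testable
    on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
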