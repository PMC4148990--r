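Package: agios
Title: Average Genomic Identity of Orthologous Gene Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the AGIOS genome-relatedness statistic for annotated
    prokaryotic genomes: orthologous gene pairs are detected between two
    genomes by reciprocal best hits over affine-gap Needleman-Wunsch protein
    alignments, the corresponding nucleotide open reading frames are globally
    aligned, and the mean percent identity over ortholog pairs summarises
    genome relatedness. Also provides genome annotation summary statistics
    (nucleotide content, gene counts, COG functional-category tables), ORFan
    classification from homology-hit tables, 16S rRNA identity thresholds for
    taxonomic rank delineation, and a truth-tracked synthetic genome-pair
    simulator for validation. Includes a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
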