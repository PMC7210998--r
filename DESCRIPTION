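Package: wgdtrace
Title: Whole-Genome Duplication Inference from Paralog Divergence
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Infers ancient whole-genome duplications (WGD) from genome
    assemblies and annotations: paralog family construction by Markov
    clustering of all-vs-all protein similarity, transversion distance at
    four-fold degenerate sites (4DTv) with multiple-hit correction,
    normal-mixture dating of duplication waves with BIC model selection,
    tandem gene cluster detection, collinear paralogon summarisation,
    k-mer based genome-size estimation, and contig curation rules
    (duplicate removal and terminal-overlap joining). Ships simulators of
    genomes with known layered-WGD history, diploid k-mer coverage
    histograms, and fragmented contig sets, so every stage can be
    exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
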