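Package: hd1survey
Title: Loss-of-Function Haplotype Surveys of the Rice Heading-Date Gene Hd1
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for rule-based loss-of-function haplotype
    classification of the rice photoperiod gene Hd1 from resequencing
    variants, together with the surrounding population-genetic machinery:
    read-pair screens for large structural insertions and small exonic
    indels, gene-model-aware variant consequence annotation,
    nucleotide-diversity and Tajima's D neutrality statistics,
    neighbor-joining trees with bootstrap support, and statistical-parsimony
    haplotype networks. A fully deterministic synthetic-data module
    generates reference loci, planted haplotypes, paired-end alignments and
    neutral coalescent cohorts so that every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    ape,
    igraph,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    VariantAnnotation,
    SummarizedExperiment,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
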