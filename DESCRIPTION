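Package: pepfam
Title: Evolutionary Analysis of Signaling-Peptide Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for studying paralog diversification in plant
    signaling-peptide gene families such as the CLE (CLAVATA3/ESR-related)
    family. Builds all-by-all peptide similarity networks with
    alignment-based edge weights, embeds them with biased random walks and
    spectral factorization, reconciles multi-resolution community
    detection into a nested gene hierarchy, fits Potts models to
    fixed-length peptide motifs by regularized pseudolikelihood to score
    mutational effects, compares paralog mutational burden against
    duplication age, groups paralogs by promoter k-mer similarity and
    semi-supervised label propagation, and calls candidate genes from
    three-population CRISPR bulk-sequencing experiments. Seeded
    synthetic-data generators with planted ground truth exercise every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
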