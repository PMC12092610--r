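Package: gotcells
Title: Genotyping of Transcriptomes and Genotype-Aware Single-Cell Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an amplicon-based genotyping-of-transcriptomes (GoT)
    workflow for a hemizygous somatic mutation in single-cell cDNA libraries,
    together with the downstream genotype-aware analyses it feeds: UMI
    collapsing by Levenshtein distance with greedy cluster absorption,
    per-UMI mutant/wild-type consensus calling and hemizygous per-cell
    genotypes; a transcriptome-read variant caller using tag filtering and a
    75 percent per-UMI consensus rule; cell quality control, marker-overlap
    cell-type annotation by Fisher's exact test, control-binned gene module
    scores and Wilcoxon differential expression; normalized mutant-cell
    frequencies and genotype-ratio curves along pseudotime with 1.96*SE
    bands; and immune-repertoire clonality statistics (Shannon entropy, Gini
    index), clone-expansion classes, somatic-hypermutation categories and
    isotype/V(D)J usage tables. A self-contained cohort simulator generates
    every input format with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
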