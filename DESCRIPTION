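Package: clonotrace
Title: Clonal Lineage Tracing of Paired Single-Cell TCR and Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing paired single-cell RNA and T-cell receptor
    (TCR) repertoires from matched tissue compartments such as brain and
    leptomeninges. Reads 10x Genomics and AIRR contig annotation tables,
    resolves cells to single complete alpha/beta chain pairs, calls clones by
    strict VDJC plus CDR3-nucleotide identity, classifies clonal expansion
    (singleton, expanded, hyperexpanded), stratifies samples by Shannon
    entropy of the clone distribution, quantifies cross-tissue repertoire
    overlap with the Morisita-Horn index, flags clones shared between tissues
    and summarises their expansion, screens expanded CDR3s for sequence
    homology by Levenshtein distance, and links clonal categories to gene
    expression through rank-sum differential expression. A seed-deterministic
    synthetic cohort generator with known ground truth supports end-to-end
    testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    withr,
    Biostrings,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
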