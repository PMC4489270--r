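Package: npprofile
Title: Normalized Phylogenetic Profiling for Protein Co-Evolution Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds normalized phylogenetic profiles (NPP) from per-genome
    BLASTP best-hit bit scores: top-hit selection, low-score and sparse-query
    filtering, self-score normalization, and per-genome Z-scoring. Detects
    putatively co-evolving proteins by Pearson correlation between Z-score
    profiles and estimates significance with a species-shuffling permutation
    null. Includes a sequence-submission mode that normalizes by the best
    genome hit and reuses precomputed per-genome statistics, a synthetic
    fixture generator with planted co-evolving modules, taxa-grouped heatmap
    and results-table output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
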