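Package: chunkcell
Title: Out-of-Core Chunked Single-Cell RNA-Seq Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A memory-lean single-cell RNA-seq analysis pipeline that streams
    row-chunked sparse count matrices through quality control, log1p
    normalization, Seurat-v3 highly variable gene selection, principal
    component analysis via Gram-matrix accumulation, Harmony batch correction
    with sparse batch designs and deterministic k-means initialization, exact
    k-nearest-neighbor graphs with Leiden clustering, tree-ensemble marker
    gene identification, and marker-overlap cluster merging. Every chunk of
    non-zero values is kept below the 32-bit indexing cap so arbitrarily
    large datasets can be processed with bounded memory, and all chunked
    statistics are exactly invariant to the chunking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    igraph,
    xgboost,
    rpart,
    uwot,
    yaml,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
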