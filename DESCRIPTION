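Package: chronet
Title: Time-Aware Chromatin Co-Accessibility Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds co-accessibility networks from longitudinal epigenomic
    signal matrices (ATAC-seq or histone ChIP-seq counts over genomic
    regions). Pairwise Spearman rank correlations are computed in
    memory-bounded chunks and persisted to a correlation-binned edge store;
    a correlation threshold is selected automatically from the relative
    size of the largest connected component; communities of co-modulated
    cis-regulatory elements are detected with the Leiden algorithm over a
    resolution grid with modularity-based selection. Communities are then
    characterized by temporal trend summaries, basal-plus-extension
    nearest-gene assignment, hypergeometric gene-set enrichment against
    the network background, genomic-class annotation fractions, and
    GIGGLE-style transcription-factor scoring. A synthetic-data generator
    with planted temporal communities supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    arrow,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
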