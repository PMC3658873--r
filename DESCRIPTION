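Package: genomaps
Title: Pre-Rendered Tile-Pyramid Maps for Biological Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts gene expression matrices, protein interaction
    networks, genome annotations and 3D tractography curve sets into
    static multi-zoom image tile pyramids plus JSON interaction
    manifests, in the XYZ slippy-map layout consumed by generic
    pan-and-zoom map widgets. Provides semantic zoom through
    zoom-linked dendrogram cuts, vertex splitting with relevance
    diffusion for network layouts, genomic glyph de-overlap with
    leader lines, empty-tile deduplication, and spatial-grid hit-test
    manifests for client-side selection, so that fully analyzable
    views can be served from a plain web directory with zero
    server-side computation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    igraph,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    GenomicRanges,
    mclust,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
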