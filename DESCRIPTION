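Package: dsbpipe
Title: Screen Hit Calling, Expression Signatures, Enrichment Maps and
    DNA-Repair Foci Scoring for Cancer Stem Cell Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reusable implementation of the computational stages of a
    glioblastoma stem-cell DNA-damage study: differential siRNA-screen hit
    calling on gamma-H2AX mean intensities (fold change over scrambled
    controls plus per-plate z-scores), RNA-seq post-processing (RPKM
    expression filtering, TMM normalization, paired differential testing,
    Benjamini-Hochberg correction, CMap-style signature extraction,
    cross-dataset Spearman concordance, mRNA half-life bias checks),
    gene-set overrepresentation with Fisher's exact test and enrichment-map
    clustering (Jaccard gene-set graph, Louvain communities, tf-idf cluster
    titling), and per-cell assay scoring (cell-cycle gating, nuclear-area
    normalized repair foci densities, the de-regulated-NHEJ score,
    population fractions, reporter repair rates, delta-delta-Ct and
    ChIP-qPCR arithmetic). Every pipeline input can be simulated in-package
    with planted ground truth, so all stages are testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    igraph,
    mclust
Config/testthat/edition: 3
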