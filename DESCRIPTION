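Package: wgdtrace
Title: Gene Family Retrieval and Synteny-Based Ohnolog Resolution Across a
    Whole-Genome Duplication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing the evolutionary history of a transcription-factor
    gene family across the Saccharomycetaceae whole-genome duplication (WGD).
    Builds a multi-genome ORF database from proteomes and gene-order tables,
    computes all-vs-all protein similarity with Karlin-Altschul e-values,
    retrieves a gene family by breadth-first traversal of the similarity network
    over an e-value exponent sweep with plateau detection, assigns
    orthologue/ohnologue roles from protein length and pre/post-WGD taxonomy,
    resolves pre- and post-WGD sub-lineages by scored gene-neighbourhood
    (synteny) analysis, scans promoters for degenerate binding-site motifs, and
    includes a WGD-aware genome-evolution simulator with ground-truth tables for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    igraph,
    mclust,
    phangorn,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
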