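Package: orthoepi
Title: Cross-Species Epigenome Comparison over Orthology-Validated Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing histone-modification landscapes between
    closely related genomes. Implements chain-based coordinate lifting with
    reciprocal one-to-one orthology validation, ChIP/input enrichment scoring
    and species-specificity classification of peak regions, bivalent-domain
    calling and promoter assignment, position-weight-matrix scanning with
    exact p-values and motif gain/loss statistics, detection of
    species-specific retrotransposon insertions with flanking-signal
    meta-profiles, LTR5 subfamily phylogenetics with a three-genome
    motif-orthology trace, and differential-expression and transposable-
    element expression summaries. A synthetic-data module generates diverged
    genome pairs with planted substitutions, insertions, peaks and
    differentially expressed genes, together with exact truth chains, for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
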