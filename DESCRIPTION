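Package: crscreen
Title: Post-Prediction Analysis of Genome-Wide Conserved RNA Structure Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the downstream analysis of genome-wide screens for
    conserved RNA secondary structures (CRSs) predicted on multiple-alignment
    blocks, as produced by structure-aware motif finders run on native and
    shuffled alignments. Implements binned false-discovery-rate estimation from
    shuffled-alignment controls, selection of high-confidence motifs,
    strand-independent merging into genomic loci, a single-label unified genome
    annotation with fractional category assignment and fold-enrichment
    statistics, recovery tables for annotated non-coding RNA classes, pairwise
    screen comparison, tiling-array style expression calling, expression
    enrichment against sampled genomic windows, co-expression scoring of
    intergenic loci with their closest gene elements, cross-species synteny
    checks, stage and cell-line enrichment of structure-containing biotypes,
    and pairwise differential-expression scoring. A synthetic-data module
    generates all pipeline inputs with planted ground truth so every stage can
    be exercised and calibrated end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, Annotation, Transcriptomics, GenomeAnnotation
RoxygenNote: 7.3.3
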