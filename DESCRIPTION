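Package: tfprio
Title: Transcription Factor Prioritisation from Co-Expression Modules,
    Motif Enrichment and Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrative workflow for identifying candidate master-regulator
    transcription factors (TFs) of a cell type of interest from transcriptomic
    meta-analyses. Expression matrices from multiple microarray platforms are
    merged, batch-adjusted with a parametric empirical-Bayes location-scale
    model, and filtered; a signed weighted co-expression network is built and
    clustered into modules via the topological overlap matrix; DNA-binding
    motifs are ranked per module by ranking-recovery AUC and normalised
    enrichment scores to assemble TF regulons; module activity is scored per
    sample with gene-set variation scores; and candidate TFs are filtered by
    differential expression, module centrality (kME) and module activity, then
    ranked by the fraction of their module they regulate. A synthetic-data
    generator with planted ground truth (modules, batches, regulons,
    differential effects) supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    limma,
    IRanges,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    mclust,
    sva,
    DESeq2,
    rtracklayer,
    optparse,
    arrow
Config/testthat/edition: 3
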