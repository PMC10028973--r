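Package: constraintkit
Title: Base-Level Evolutionary Constraint Calling and Constraint-to-Disease Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls evolutionarily constrained bases from per-base conservation
    score tracks (signed -log10 p-values in the phyloP convention) by
    genome-wide Benjamini-Hochberg thresholding, and propagates constraint into
    downstream disease-genetics statistics: allele-frequency-spectrum summaries
    and depletion tests for germline variants, per-gene constraint metrics
    (fraction of constrained CDS bases, binomial excess-constraint z,
    covariate-adjusted residual constraint, alignment-column entropy, deciles,
    density-based outlier genes), copy-number-variant constrained-base burden
    testing, a somatic non-coding constraint mutation (NCCM) recurrence scan
    for candidate cancer driver loci, and detection of unannotated intergenic
    constraint regions (UNICORNs) with matched background sampling and
    fine-mapping PIP comparisons. A seeded synthetic-genome simulator with
    serialized ground truth makes every stage testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    seqinr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
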