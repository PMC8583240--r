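Package: lncforge
Title: Discovery and Characterization of Novel Long Noncoding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A toolkit for discovering novel long noncoding RNAs (lncRNAs)
    from assembled transcriptomes and characterizing them. Candidate
    transcripts are classified against a reference annotation with
    gffcompare-style class codes, filtered by a multi-criteria novelty rule
    (prevalence, length, exon count, class code, coding potential,
    chromosome), cross-validated between sequencing platforms by
    intron-chain identity, and partitioned into known versus novel by
    re-annotation against updated databases. Downstream characterization
    covers per-exon conservation profiling from base-wise score tracks,
    paired pre/post differential-expression selection, unsigned weighted
    co-expression networks with module eigengenes and hub calling, and
    cis-eQTL exon/SNP overlap. A deterministic synthetic-fixture generator
    with planted ground truth supports testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    data.table,
    stats,
    utils,
    methods,
    jsonlite,
    yaml,
    glmnet,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
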