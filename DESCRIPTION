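Package: lncnet
Title: Long Non-Coding RNA Discovery, Differential Expression and
    Regulatory Co-Expression Networks from Bulk RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the transcriptome analysis of skeletal
    muscle under prenatal (maternal-nutrition) programming: Cufflinks-style
    class-code annotation of assembled transcripts against a reference,
    a sequential long non-coding RNA (lncRNA) identification cascade
    (length, open reading frame, protein homology, coding potential, exon
    structure), TMM-normalised negative-binomial differential expression
    for lncRNA and for a curated epigenetic gene panel, regulatory impact
    factor (RIF1/RIF2) scoring of lncRNA against Gene Ontology selected
    muscle genes, and partial-correlation-and-information-theory (PCIT)
    co-expression networks contrasted across treatments. A synthetic-data
    generator with known ground truth makes every stage testable without
    access to the original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    edgeR,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
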