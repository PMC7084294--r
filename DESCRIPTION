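Package: lincpipe
Title: Identification of Long Intergenic Non-Coding RNAs and Prediction of
    Their Target Genes from Assembled Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for calling long intergenic non-coding RNAs
    (lincRNAs) from a merged transcriptome assembly and characterising their
    regulatory potential. Candidate transcripts are classified as intergenic
    against a reference annotation, passed through a six-stage filter cascade
    (intergenic location, exon/length structure, coding potential on both
    strands, protein-domain homology, protein-database homology, expression),
    and split into known and novel lincRNAs by exonic overlap with a lincRNA
    database. Downstream stages provide two-group differential expression on
    counts, co-localization of differentially expressed lincRNAs with QTL
    intervals, cis (neighbourhood) and trans (expression-correlation) target
    prediction with Benjamini-Hochberg FDR control, and export of signed
    lincRNA-target co-expression networks. A seeded synthetic-data generator
    with planted ground truth makes every stage testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
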