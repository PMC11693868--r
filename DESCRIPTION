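Package: ribosel
Title: Translatome and Transcriptome Co-Profiling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint analysis of cytosolic (transcriptome) and
    ribosome-associated (translatome) RNA-seq quantifications across two
    conditions: differential expression and differential translation calling
    under replicate-free designs, gene-level translational efficiency with
    rank normalization and threshold-based differential-TE calls, a per-gene
    chi-square framework for ribosome-selective transcript isoform usage with
    a Diff_CP selection score, dominant-transcript switch detection, UTR/CDS
    structural comparison of extreme isoforms, hypergeometric gene-set
    enrichment, and a negative-binomial simulator with planted effects that
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
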