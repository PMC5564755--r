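Package: fusionNominate
Title: Nomination of Recurrent, Tumor-Enriched Fusion Transcripts from RNA-Seq Cohorts
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cohort-level nomination of recurrent, tumor-enriched chimeric RNAs
    from per-sample fusion-call tables (deFuse-style TSV) and expression data.
    Implements a successive filter cascade (read-support screening, tumor
    recurrence, one-sided Fisher exact enrichment against matched benign
    samples, a paired signed-rank overexpression gate, multimapping-ratio and
    biotype/overlap filters), breakpoint split-read RPKM quantification,
    junction annotation (splice-site concordance, read-through classification,
    reading-frame and fusion-peptide prediction, domain retention), 3'-partner
    expression association, Pearson-distance hierarchical clustering of
    normalized differential expression profiles, and a seeded synthetic-cohort
    generator with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
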