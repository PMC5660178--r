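Package: lncscout
Title: Discovery, Filtering and Quantification of Long Non-Coding RNAs from Assembled Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extracts novel long non-coding RNA (lncRNA) candidates from
    per-sample assembled transcript models (StringTie-style GTF) by
    strand-aware comparison against a reference annotation, applies a
    filter cascade (length bounds, repeat overlap for single-exon
    candidates, sample-specific expression cutoffs referenced to known
    transcripts), assesses coding potential with two independent
    feature-based logistic scorers combined by union or intersection,
    consolidates candidates across samples into a unified annotation,
    quantifies known and novel lncRNAs from fragment records (raw counts
    and RPKM), annotates each lncRNA with its nearest protein-coding
    gene, and evaluates recovery by withholding known lincRNAs. Includes
    a synthetic-data generator that produces fully self-contained
    fixtures (genome, annotation, repeats, planted novels and decoys,
    per-sample assemblies and fragments) with machine-readable ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
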