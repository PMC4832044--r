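Package: clocktide
Title: Circadian Analysis of Paired Ribosome-Profiling and RNA-Seq Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for detecting daily rhythms in transcription and
    translation from paired ribosome-profiling (RPF-seq) and RNA-seq
    time-course experiments. Covers footprint read preprocessing (adapter
    trimming, size filtering, ordered contaminant depletion), per-gene
    quantification over 5'UTR/CDS/3'UTR annotation features, upper-quartile
    count normalization with RPKM and translation-efficiency computation,
    rhythmicity detection by fixed-period cosinor and circularized sigmoid
    model fitting with BIC model selection and Benjamini-Hochberg FDR, and
    classification of genes into transcriptional versus translational rhythm
    categories. A synthetic-data generator emulates an around-the-clock
    mouse liver study design (12 time points every 2 h, 2 replicates) with
    planted rhythms and negative-binomial noise so the full pipeline is
    testable without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    Rsamtools,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
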