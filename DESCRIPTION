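Package: cotfinder
Title: Co-Transcription-Factor Inference from RNA-Seq and ATAC-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Explains loss of a target gene's expression after a
    chromatin-remodeler perturbation by integrating negative-binomial
    differential expression testing, ATAC-seq consensus peaks and
    differential promoter openness, a curated TF regulon, physical
    protein-protein interactions, and promoter motif scanning into a
    two-hypothesis inference: a direct regulator changes (hypothesis I),
    or a differentially expressed co-transcription factor physically
    coupled to an unchanged direct regulator changes (hypothesis II).
    Ships a seeded multi-omic simulator with planted ground truth that
    emulates a two-cell-line CRISPR clone design, plus the small
    statistics layer used for cohort summaries and cytotoxicity assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
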