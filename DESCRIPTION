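Package: sncatlas
Title: Single-Cell Small RNA-Seq Quantification and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of the computational pipeline used to
    build single-cell small non-coding RNA (sncRNA) expression atlases from
    Small-seq libraries: UMI extraction and adapter/polyA trimming, best-stratum
    short-read placement with length-dependent mismatch filters and recursive
    3'/5' soft-clip rescue, directional UMI deduplication with remapping,
    hierarchical strand-aware biotype annotation, isomiR and tRNA-derived
    fragment classification, cell quality control, normalisation and
    Wilcoxon-based marker/differential-expression statistics, cross-branch
    pseudotime rescaling with trajectory-associated miRNA selection and
    expression-pattern clustering, miRNA-target anticorrelation testing, and a
    four-criterion filter for novel miRNA candidates. A synthetic-data module
    generates a toy genome, annotation tracks and Small-seq-structured FASTQ
    with planted per-molecule ground truth so that every stage can be verified
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
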