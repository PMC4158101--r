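Package: clonaltrace
Title: Clonal Evolution of B-Cell Lymphoma from VDJ Repertoires and Paired Exomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@clonaltrace.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for tracing clonal evolution between matched
    diagnosis and relapse B-cell lymphomas. Annotates immunoglobulin
    heavy-chain VDJ junctions in deep amplicon reads by seeded ungapped
    alignment against a germline segment library, profiles somatic
    hypermutation (SHM) subclones within the dominant rearrangement, builds
    neighbor-joining trees over subclone SHM profiles and classifies each
    tumor pair as early- or late-divergent, tests paired-exome variant tables
    for gained and lost SNVs with Benjamini-Hochberg false discovery control,
    segments exon-level copy-number log2 ratios by circular binary
    segmentation, and models background error for ultra-deep minor-clone
    detection. A synthetic-data generator with known ground truth emulates
    the clonal structure of diagnosis-relapse pairs so every stage can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
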