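Package: peaklink
Title: Linking Accessible Chromatin to Genes in Regeneration Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Batch tools for integrating ATAC-seq peak calls with time-course
    RNA-seq in regenerating tissue. Derives significance-filtered 500bp
    "peaklets" anchored on peak-signal modes, classifies them as proximal or
    distal to transcript start sites, exports many-to-many peaklet-gene
    correspondences (CSV/BED/FASTA) for downstream motif analysis, transforms
    and clusters time-course expression matrices, tests GO term
    over-representation against an expressed-transcript universe, and projects
    gene sets across species through homology tables. Includes a deterministic
    synthetic-data generator with known ground truth so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
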