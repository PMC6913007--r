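Package: TEforge
Title: Simulation, Filtering and Base-Pair Benchmarking of Transposable
    Element Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for constructing and evaluating transposable element (TE)
    libraries. Provides a base-pair-resolution benchmarking framework that
    scores a test TE annotation against a curated annotation with six
    confusion-matrix metrics; a multi-stage filtering cascade that turns
    noisy raw TE candidates (tandem-repeat contamination, shifted
    boundaries, misclassified or structurally invalid elements) into a
    clean, non-redundant, classified library; a k-mer seeded homology
    masker for annotating genomes with a library; and a genome simulator
    that plants structurally faithful LTR, TIR/MITE, Helitron and
    LINE/SINE copies (terminal motifs, target-site duplications, nesting,
    truncation, divergence) with full ground truth, so every component is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, Annotation, Alignment, Transposon, Sequencing
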