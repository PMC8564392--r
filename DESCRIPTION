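Package: attractome
Title: Data-Driven Boolean Network Attractors from Single-Cell Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assembles signed gene regulatory networks from expression,
    interactome, transcription-factor and pathway tables, assigns nested
    canalyzing Boolean rules to every node, binarizes per-cell expression
    with a step-function (BASC-style) threshold algorithm, simulates
    synchronous Boolean trajectories from each cell's binarized state to
    its attractor, and calls per-group constantly expressed or silent
    genes with a 95%-of-cells consensus rule. Includes synthetic-data
    generators with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Matrix,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
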