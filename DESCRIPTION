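Package: neoloopscan
Title: Hi-C 3D-Genome Alteration Analysis with Translocation and Neo-Loop Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-sample Hi-C cohorts: contact-matrix
    binning and Knight-Ruiz balancing, A/B compartment eigenvector tracks with
    majority-rule consensus and switch calling, insulation-score TAD boundaries
    and domain scores with differential tests, focal chromatin-loop calling with
    aggregate peak analysis and distance-stratified differential loops,
    interchromosomal translocation detection with single-base-pair breakpoint
    refinement from chimeric reads, reassembled-map neo-loop (enhancer
    hijacking) detection, virtual 4C, and integration of structural changes
    with differential gene expression. Includes a seeded synthetic-cohort
    generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
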