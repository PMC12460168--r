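Package: nucleoidC
Title: Ultra-High-Resolution Contact-Map Analysis of the Bacterial Nucleoid
Version: 0.1.0
Authors@R:
    person("Nucleoid", "Tools", email = "nucleoidc@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for ultra-high-resolution chromosome conformation
    capture (Micro-C) maps of a single bacterial chromosome. Provides sparse
    contact-matrix handling with ICE (iterative correction) balancing,
    distance-decay expected models and scaling curves, stratum-adjusted
    replicate correlation (SCC), local rescaled average contact maps
    (pile-ups) and strand-oriented 1D meta-profiles, a promoter-terminator
    (TSS-TES) contact statistic with random-interval expected models, a
    Monte-Carlo interval shuffle colocalization test, transcription-activity
    estimation from RNA-DNA (Red-C) contacts, and detectors for chromosomal
    hairpins (CHINs), hairpin domains (CHIDs) and operon-sized contact
    domains (OPCIDs). A fully parameterized synthetic-nucleoid generator
    plants all of these structures with known ground truth so that every
    stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
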