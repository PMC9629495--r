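Package: fragphase
Title: Fragment-Based Molecular Replacement with Model-Free Verification
    on Toy Crystals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Preparation and geometric decomposition of predicted protein
    models into spherical search fragments, crystallographic figures of
    merit (correlation on normalized intensities, weighted mean phase
    differences, map correlation, expected LLG), reciprocal-space phase
    clustering with origin-shift alignment, model-omission verification
    of molecular-replacement solutions, and multicopy prioritization.
    The whole workflow runs on synthetic toy crystals through a pluggable
    expansion backend, so every stage is testable without external
    crystallographic binaries.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
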