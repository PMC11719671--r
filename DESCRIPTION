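Package: angioring
Title: Standardized Quantification of Aortic Ring Assay Vessel Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the standardized quantification of ex vivo aortic ring
    assay outgrowth. Provides domain types for explant vessel networks (ring,
    initial vessels, branches, junctions, loops), twelve operationally defined
    network parameters in four subindex categories (explant, pattern, network
    properties, sprouting), a control-normalized Angiogenic Activity Index
    (AAI) with weighted subindices and a radar-style angiogenic profile, a
    skeleton-image-to-network extractor for binary vessel masks, and a
    stochastic outgrowth simulator with treatment-dependent growth and
    branching multipliers so the full analysis pipeline is testable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    png,
    ggplot2,
    rlang,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
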