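Package: omrplate
Title: Multi-Well Optomotor Response and Visual Startle Assays for
    Zebrafish Larvae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for running and analysing the multi-well optomotor
    response (OMR) visual-impairment assay in zebrafish larvae entirely in
    silico: generation of the moving-grating stimulus animation, a
    circular-well area-partition scoring system with post-stimulus change
    scores, an agent-based larval behaviour simulator with phenotype
    presets, a synthetic plate-image renderer with automated well and larva
    detection, the assay's statistical battery (Bowker's test of symmetry,
    exact binomial sign test, Wilcoxon-Mann-Whitney, one-way ANOVA), and a
    startle-response counter for light-interruption activity traces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
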