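Package: vasctum
Title: Hybrid Cellular Automaton Model of Vascular Tumour Growth and
    Vascular-Targeting Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates glioblastoma growth in a vascularized tissue with a
    two-dimensional hybrid cellular automaton. Automaton cells are the Voronoi
    regions of a random-sequential-addition hard-disk point process; a
    randomized Krogh-type capillary network supplies the tissue; an
    eight-species VEGF/angiopoietin/Tie-2 reaction-diffusion system couples
    tumour hypoxia to vessel cooption, regression and angiogenic sprouting.
    Includes three vascular-targeting treatment protocols (an angiogenesis
    inhibitor, the inhibitor combined with cytotoxic chemotherapy, and a
    vascular disrupting agent), replicate averaging, treatment-parameter
    sensitivity sweeps and snapshot rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    png,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
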