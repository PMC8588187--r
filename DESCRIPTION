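Package: casenmr
Title: Computer-Assisted Structure Elucidation from NMR Correlation Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale engine for computer-assisted structure elucidation
    (CASE) of small organic molecules. From a molecular formula and 1D/2D NMR
    correlation tables (HSQC, COSY, HMBC), it builds a molecular connectivity
    diagram, exhaustively generates all constitutional isomers consistent with
    the constraints, handles contradictory long-range ("non-standard")
    correlations by fuzzy structure generation, ranks candidates by empirical
    carbon-13 chemical-shift prediction (additive increments and HOSE-style
    environment codes), supports user fragment databases, and selects relative
    stereochemistry from NOE distance-class constraints over embedded
    conformers. A forward simulator of correlation tables makes the full loop
    testable from known structures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    yaml,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
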