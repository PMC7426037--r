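Package: exposnet
Title: Growing Semantic Networks from Expositional Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts concept co-occurrence networks from expositional
    plaintext (textbook chapters, lecture notes) and analyses how their
    structure unfolds sentence by sentence. Concepts are identified with a
    frequency-penalized variant of rapid automatic keyword extraction
    (RAKE); the growing network is represented as an expositional
    filtration whose meso-scale architecture (core-periphery, periphery
    communities, group introduction curves) and topological knowledge gaps
    (persistent homology of the clique-complex filtration, barcodes, Betti
    curves, normalized average cycle lifetimes) are quantified and
    compared against five null models. Includes a synthetic-document
    generator with planted core-periphery and community structure for
    validation, and a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    stringi,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
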