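Package: knotscan
Title: Detection and Localization of Composite Knots in Protein Backbones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for deciding the knot type of open and closed protein
    backbone curves and for finding doubly knotted (composite trefoil,
    3_1#3_1) proteins. Implements Koniaris-Muthukumar-Taylor (KMT) chain
    reduction, stochastic chain closure, exact Alexander-determinant knot
    invariants evaluated at t = -1 and t = -2, subchain fingerprinting with
    knotted-core localization and slipknot detection, a Pfam-style
    domain-architecture screen for proteins able to carry two knots,
    Shrake-Rupley solvent-accessible surface areas with buried interface
    area for dimer interfaces, and synthetic generators (parametric torus
    knots, braid closures, connected sums, slipknots, annotation tables
    with planted architectures) that provide ground truth for every step.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
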