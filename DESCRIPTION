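Package: hookmorph
Title: Morphometry and Discriminant Analysis of Diplozoid Haptoral Hooks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for landmark-based morphometry of the haptoral central
    hooks of diplozoid monogeneans (Platyhelminthes: Diplozoidae) and for the
    statistics used to discriminate species from those measurements. Computes
    14 point-to-point hook and handle measurements (lengths, widths, curve
    depths and aperture angles) from digitized sclerite outlines, simulates
    parametric hook shapes with brute-force ground truth, draws measurement
    tables from published per-species summary statistics for Paradiplozoon
    vaalense, Diplozoon paradoxum and Paradiplozoon ichthyoxanthon, and runs
    Kruskal-Wallis post hoc tests, univariate Wilks' Lambda equality-of-means
    tests, forward stepwise linear discriminant analysis with canonical
    functions and structure matrix, and classification with leave-one-out
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
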