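Package: pepdigest
Title: Peptide Digest Profiling and Model-Based Clustering of Dietary Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating in vitro dietary protein digests against a
    benchmark protein from LC-MS peptide ion-peak tables. Implements raw
    abundance filtering, enzyme-blank subtraction, benchmark ion matching
    under charge/m-over-z/retention-time tolerances with a weighted
    two-dimensional nearest-match distance, derivation of per-digest
    characteristics (size-class abundance fractions, total abundance, unique
    ions, benchmark overlap percentages), Grubbs outlier screening and
    benchmark-comparison statistics for biological read-outs, and holistic
    model-based clustering via Gaussian mixtures with the fourteen
    eigen-decomposed covariance parameterizations selected by BIC. Includes
    seeded synthetic-data generators with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
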