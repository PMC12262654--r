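Package: nncsr
Title: Permutation-Free Complete Spatial Randomness for the Nearest-Neighbor G Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Closed-form mean and variance of the nearest-neighbor G function
    for a randomly marked subset of observed point locations, the
    sample-specific complete spatial randomness (CSR) null used in marked
    point-pattern analysis (e.g. cell phenotypes in multiplex
    immunofluorescence). Provides the exact hypergeometric expectation and
    variance of G(r) over all size-n subsets of N observed points, permutation
    and exhaustive-enumeration baselines for validation, a normal-approximation
    deviation test with CSR confidence bands, seeded synthetic pattern
    generators, and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
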