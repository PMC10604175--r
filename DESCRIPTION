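Package: pilcbscso
Title: Binary Sand Cat Swarm Optimization with Pinhole-Imaging Learning and
    Crossover for Gene Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection for two-class, high-dimensional
    expression matrices. Implements the binary sand cat swarm optimizer
    (BSCSO) and its enhanced variant PILC-BSCSO, which fuses single-point
    crossover and pinhole-imaging opposition-based learning into the swarm
    loop. Candidate gene subsets are scored by the Cohen's kappa of a
    linear-kernel support vector machine under repeated stratified
    cross-validation. Includes a differential-expression prefilter (Welch t
    with Benjamini-Hochberg correction), a synthetic expression-matrix
    generator with planted signal for end-to-end testing, delimited-text
    readers and writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
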