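Package: envepi
Title: Environmental Interactions and Epistasis in Factorial
    Stimulus-Response Experiments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models quantitative omics responses (log2 fold changes) to two
    concurrent environmental stimuli in a 2x2 factorial design, classifies
    each feature into environmental-interaction classes (dominance,
    non-specific response, discordance, suppression) by analogy with gene
    interaction, and tests for environmental epistasis as a deviation of the
    concurrent-stimulus response from the sum of the single-stimulus
    responses. Also builds a sparse partial-correlation coexpression network
    with power-law and hub diagnostics, estimates microbial doubling times
    from growth curves with an additivity test for concurrent stimuli, and
    ships a synthetic-data generator with known ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
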