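Package: craniomod
Title: Allometry and Heterochrony of the Two Cranial Modules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for craniometric heterochrony studies of the
    hominid skull. Implements size-scaled two-block partial least squares of
    the neurocranial and splanchnocranial modules, correlation-matrix factor
    analysis with the isometric-vector diagnostic, reduced major axis (RMA)
    allometric regression with Clarke's slope test and intercept comparison,
    ontogenetic trajectory angles, decomposition of between-group differences
    into ontogenetic scaling and lateral transposition, encephalization
    quotient association analysis, a measurement-error robustness simulation,
    and a synthetic craniometric data generator emulating multi-group
    log-linear allometric growth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    boot
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
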