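Package: uniplant
Title: Universal-Factors Model for Embryo Transfer Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and validates a universal-factors model of human embryo
    transfer outcomes. Embryos transferred together implant independently
    only when transfer-level ("universal") conditions are favorable, which
    happens with probability UNI; per-embryo live birth rates are estimated
    by least squares over moving age groups and four transfer categories
    (fresh/frozen x cleavage/blastocyst), and UNI is fitted by maximum
    likelihood over singleton outcomes of multiple-embryo transfers.
    Includes exact outcome distributions for transfers of any size,
    tenfold cross-validation with parametric-bootstrap predictive
    distributions, counseling tables with multiples-risk shading, a
    synthetic clinic simulator, and a sample-size study for the precision
    of the fitted UNI.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
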