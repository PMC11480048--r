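Package: rqtwin
Title: Respiratory-Quotient Control of Hypoxic Fed-Batch Cultures with a
    Digital-Twin Bioreactor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digital-twin simulation and physiological control of hypoxic,
    carbon-limited fed-batch cultivations of recombinant Pichia pastoris.
    Implements a two-reaction stoichiometric twin of oxygen-transfer-limited
    metabolism, off-gas soft sensors for the oxygen uptake rate, carbon
    dioxide evolution rate and respiratory quotient (RQ), three RQ
    controllers acting on the agitation rate (a manual-heuristic emulation,
    a Boolean-logic controller and an adaptive-proportional controller whose
    gain is supplied by a random-forest model), controller performance
    statistics (mean relative error, root-mean-square deviation, recovery
    time, band occupancy), and weighted-least-squares reconciliation of the
    seven specific rates under carbon and degree-of-reduction balance
    constraints with a chi-squared consistency test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
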