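Package: leaflapse
Title: Temporally Separated Optimality Modelling of Leaf Gas Exchange
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Deterministic simulator of leaf gas-exchange trait dynamics across
    response timescales, combining Farquhar-von Caemmerer-Berry photosynthesis,
    least-cost optimal ci:ca (the 'P model'), instantaneous stomatal
    optimization under a constant marginal water cost, coordinated acclimation
    of carboxylation capacity, and the anatomical maximum stomatal conductance
    constraint. An environmental step change (CO2 or vapour pressure deficit)
    is replayed through five labelled states, from the initial optimum through
    second-, minute-, week- and season-scale adjustments, producing raw and
    normalized trait time-lapses. Ships a machine-readable catalog of reviewed
    leaf traits with their response mechanisms and timescale bands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
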