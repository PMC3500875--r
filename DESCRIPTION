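Package: dynpath
Title: Dynamic Path Analysis and Local Independence Graphs for Event-History Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a dynamic, process-based view of causality and mediation.
    Implements path-specific direct and indirect effects in linear (stochastic)
    differential systems via node splitting and matrix exponentials; local
    independence graphs with the delta-separation criterion (ancestral restriction,
    edge deletion, moralization); dynamic path analysis for event-history data
    combining additive-hazard least-squares increments with per-event-time mediator
    regressions into cumulative direct, indirect and total effect curves; and the
    linear increment model for longitudinal panels, including a direction-specific
    local-dependence test. A synthetic-data module generates counting-process and
    panel data with known structure so every estimator is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
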