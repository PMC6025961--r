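Package: metaswitch
Title: Dynamic Metabolic Subpopulations in Clonal Bacterial Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantification of dynamic metabolic
    subpopulations in clonal bacterial cultures. Provides an agent-based
    two-reporter state-switching simulator (batch culture, mother-machine
    microfluidics, and agarose-pad microcolonies) in which acetate-secreting
    competent cells and acetate-detoxifying acetoin producers interact
    through a shared environment; snapshot-level statistics (skewness
    screening, 2-standard-deviation positive-cell classification,
    fraction-positive time courses, Hill dose-response fits); lineage-level
    estimators (threshold-crossing activation events, dwell times, events
    per 100 hours, exponential elongation rates, per-state growth
    comparison, genealogy trees with Newick export, dual-reporter
    correlation); and metabolite phase detection for acetate
    production/consumption dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    readr,
    jsonlite,
    yaml,
    ape,
    minpack.lm,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
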