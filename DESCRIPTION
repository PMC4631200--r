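Package: stressGI
Title: Genetic-Interaction Analysis of a Stress-Reporter Screen
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of reporter-gene genetic-interaction
    screens of the yeast general stress response. Processes flow-cytometry
    event streams (well demultiplexing, automatic FSC/SSC density gating,
    median extraction, autofluorescence correction, replicate averaging)
    into a strain-by-condition expression matrix; classifies
    condition-specific knockout effects; scores Msn2/4 dependence of each
    perturbation from triple-mutant expression; calls masking epistasis and
    cross-condition consensus; fits additive, multiplicative, and combined
    additive-multiplicative genetic-interaction models by constrained least
    squares; and quantifies transcription-factor nuclear localization
    dynamics as the area under the nuclear-to-cytoplasmic ratio time
    course. A ground-truthed synthetic-data generator emulates per-cell
    log-normal reporter distributions, scatter clouds with outliers, timed
    plate streams, and pulsatile localization traces, so the full pipeline
    is testable without instrument data. Includes a dilution-series planner
    for landing strains of unknown growth rate in a target optical-density
    window.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
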