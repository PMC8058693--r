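Package: chemoepisodes
Title: Regimen-Level Chemotherapy Episode Abstraction for OMOP-CDM Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Abstracts regimen-level chemotherapy episodes from
    ingredient-level drug exposure records in OMOP Common Data Model
    (v5.3) shaped tables. Ships a machine-readable JSON knowledge base of
    regimen definitions (index, combination and exclusion drug roles plus
    cycle and treatment-line time windows), a temporal matching engine
    that identifies treatment cycles, collapses them into treatment
    episodes and assigns treatment lines, a writer for the OMOP oncology
    extension EPISODE and EPISODE_EVENT tables, a synthetic cohort
    simulator with ground truth for validation, and downstream analytics:
    treatment-pattern summaries, treatment trajectories, timing of
    chemotherapy-induced neutropenia and febrile neutropenia, and
    validation metrics (positive predictive value, cycle-count accuracy,
    mean absolute error, root mean square error).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
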