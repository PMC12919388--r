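Package: gestsynth
Title: Synthetic Maternal-Health Cohorts for the Colombian Gestation Care
    Pathway
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Generates fully synthetic longitudinal clinical records for
    pregnant women following the Colombian antenatal care pathway. A generic
    clinical state-machine engine executes a JSON-defined gestation module
    (prenatal controls, trimester-anchored complication gates, procedures and
    vaccinations) whose gate probabilities are calibrated so that cohort-level
    condition frequencies reproduce a reference 10,637-woman cohort.
    Demographics are sampled from DIVIPOLA-coded municipality population
    weights. Cohorts export to OMOP Common Data Model v5.4 CSV tables with
    Colombian location handling, and a validation report recomputes observed
    condition frequencies against literature reference ranges.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
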