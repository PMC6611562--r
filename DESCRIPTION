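Package: vocepi
Title: Vaso-Occlusive Crisis Episode Construction and Utilization
    Analysis from Administrative Claims
Version: 0.1.0
Authors@R:
    person("Vocepi", "Maintainers", email = "vocepi@example.org",
           role = c("aut", "cre"))
Description: Builds vaso-occlusive crisis (VOC) episodes of care for sickle
    cell disease (SCD) patients from administrative claims: ICD-9 code-set
    driven cohort selection with index dating and continuous-enrollment
    requirements, gap-threshold merging of VOC claims into episodes,
    hierarchical place-of-service assignment, complicated/uncomplicated
    episode classification, primary-reason attribution for emergency-room
    and inpatient visits, length-of-stay statistics, and person-year rate
    reporting.  Includes a synthetic Medicaid-like claims generator with
    known ground truth so every pipeline stage has a recoverable target.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
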