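Package: wyloss
Title: Working Life Years Lost to Sickness Absence, Mortality, and
    Ill-Health Retirement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Person-time accounting engine for quantifying disease burden in
    the workplace as working life years lost per 10,000 person-years of
    working time ("per myriad"). Clips long-term sickness-absence spells,
    deaths and ill-health retirements against a study observation window and
    each employee's 20th-to-60th-birthday span, groups diagnoses into ICD-10
    chapter categories (with external causes merged and intentional self-harm
    separated), aggregates the losses into stratified per-myriad tables with
    Poisson confidence intervals, and ships a seeded synthetic occupational
    cohort simulator so the full pipeline can be exercised without
    confidential HR records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    lubridate,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
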