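Package: ehpgap
Title: Need, Coverage and Cost-Effectiveness Assessment of Essential
    Health Packages
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to assess an essential health package (EHP) delivered
    under a sector-wide approach: burden-of-disease ranking and
    incidence-derived need estimation (DALYs with optional time
    discounting), conversion of routine health-management-information-
    system (HMIS) service counts into rates per 1000 of the appropriate
    denominator population, provision-to-need gap ratios with
    over/under-provision classification, screening of interventions
    against a dollars-per-DALY cost-effectiveness threshold crossed with
    burden rank, and per-capita funding coverage analysis.  Ships
    transcriptions of the Malawi 2008 EHP assessment tables as packaged
    fixtures and a synthetic-data generator with known ground truth for
    end-to-end pipeline validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
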