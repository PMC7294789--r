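Package: lrckit
Title: Familial Longevity Scoring from Cohort Life Tables and Pedigrees
Version: 0.1.0
Authors@R:
    person("LRC", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools to quantify the familial aggregation of human longevity.
    Builds sex- and birth-cohort-specific survival percentiles from cohort
    life tables, computes the Longevity Relatives Count (LRC) score -- the
    kinship-weighted proportion of a person's ancestral blood relatives who
    reached the top survivors of their birth cohort -- and classifies
    individuals into family cases and controls. Supports standardized
    mortality ratios with exact chi-square confidence limits and a
    family-resampling bootstrap, shared gamma-frailty proportional-hazards
    contrasts with left truncation, and a synthetic multigenerational cohort
    simulator for validation when real genealogical data are restricted.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
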