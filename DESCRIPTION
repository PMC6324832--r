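Package: geomorbid
Title: Ecological Analysis of Areal Co-Prevalence from Hospital Discharge Data
Version: 0.1.0
Authors@R: person("Analytics", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for ecological (areal) studies of the geographic
    overlap between two hospital-treated conditions, built around French-style
    administrative discharge data. Provides ICD-10 case ascertainment from
    stay-level records with deduplication to unique patients, direct age-sex
    standardization of areal prevalence per 100,000 inhabitants, a bidimensional
    material/social deprivation index (Pampalon-style five-level crossing of
    z-scored census indicators), High/Low co-prevalence classification against
    national reference rates, and bidirectional tertile-based ecological
    logistic regression with in-house maximum likelihood and Wald inference.
    A seeded synthetic-data generator emulates the structure of the source
    databases (heterogeneous areal populations, decennial age-sex strata,
    correlated latent deprivation, urban typology, duplicate stays and a shared
    area-level frailty inducing co-prevalence) so that every stage is testable
    and parameter recovery is measurable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
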