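Package: opioidlca
Title: Subtyping Opioid Misuse in Hospitalized Patients with Latent Class
    Analysis of Electronic Health Record Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A prognostic-enrichment pipeline for opioid misuse in hospital
    encounters. Simulates a seeded synthetic electronic-health-record cohort
    with a latent four-class structure; applies a rule-based operational
    definition of opioid misuse over urine drug screens, medication events,
    and diagnosis codes; discovers misuse subtypes with a from-scratch latent
    class analysis (EM estimation, BIC/aBIC/cAIC model selection over one to
    eight classes, posterior class assignment); validates subtypes with latent
    Dirichlet allocation over concept-identifier bags from clinical notes; and
    compares 30-day unplanned readmission and discharge dispositions across
    subtypes using CMS-style index and readmission rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
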