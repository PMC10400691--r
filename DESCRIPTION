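Package: icutriage
Title: Simulation of Ex-Ante and Ex-Post Triage Policies on the Intensive Care Unit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Patient-level Monte-Carlo simulation of intensive-care bed
    rationing under surge conditions. Patients with and without comorbidities
    receive death probabilities drawn from triangular distributions whose means
    are scaled by literature-based relative death risks; six allocation
    policies (combinations of random or prognosis-based initial allocation
    with random or ex-post prognosis-based reallocation) are compared by the
    prospective mortality of the treated cohort over repeated reallocation
    time points. Includes exact density-overlap computation for triangular
    distributions, a seeded replication engine with a sensitivity grid, and
    one-way ANOVA with post-hoc tests over replication-level mortality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
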