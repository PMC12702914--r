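Package: rrmsbia
Title: Budget Impact Modelling of Disease-Modifying Therapies for
    Relapsing-Remitting Multiple Sclerosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A static five-year budget impact model for disease-modifying
    therapies (DMTs) in relapsing-remitting multiple sclerosis (RRMS) from a
    national payer perspective.  Projects the treatment-eligible population
    through a multiplicative epidemiological cascade into five activity and
    treatment-history subgroups, decomposes per-patient annual costs into
    acquisition, administration, monitoring, adverse-event and relapse
    components, reduces managed entry agreements (fixed discounts and
    free-goods patient splits) to effective acquisition discounts, and reports
    the net budget impact of new interventions against a standard-of-care
    basket under expert market-share and full-uptake scenarios.  Includes
    one-way (tornado) sensitivity analysis over the epidemiological
    parameters, a seeded synthetic-input generator emulating the structure of
    confidential national cost and epidemiology inputs, and published
    component-decomposition rows packaged as regression fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
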