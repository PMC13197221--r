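Package: dentalmix
Title: Needs-Led Skill-Mix Workforce Modelling for Child Dental Care
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Sizes the dental workforce needed to deliver evidence-based,
    caries-risk-stratified preventive care to the child population of
    England under alternative skill-mix (task delegation) scenarios.
    Demand is built from an age-banded population, high-caries-risk
    proportions and per-child annual care timings (with amortised fissure
    sealants and age/risk-dependent fluoride-varnish frequencies);
    clinician capacity converts NHS working patterns into annual clinical
    minutes per whole-time equivalent; a linear programme then minimises
    the total workforce subject to each cadre's capacity meeting its
    assigned demand.  Includes six built-in delegation scenarios, a
    2023-2050 projection pipeline with a declining risk-rate trajectory,
    a synthetic-input generator for end-to-end testing, and a closed-form
    verification oracle for the optimiser.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
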