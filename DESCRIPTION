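Package: ceanet
Title: Markov Cohort Cost-Effectiveness Modelling of Radionuclide Therapy for
    Advanced Neuroendocrine Tumours
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A three-state (stable disease, progressive disease, dead) Markov
    cohort model for the cost-effectiveness of Lutetium-Octreotate peptide
    receptor radionuclide therapy versus high-dose Octreotide long-acting
    release in advanced midgut neuroendocrine tumours, from the Dutch
    healthcare perspective. Provides pseudo individual-patient-data
    reconstruction from digitized Kaplan-Meier curves with numbers at risk,
    parametric survival fitting and extrapolation, hazard-ratio application,
    background-mortality override from a life table, discounted cost and QALY
    accumulation, ICER and net-monetary-benefit computation, proportional
    shortfall classification, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, one-way tornado analysis, and
    named scenario runs. Includes a synthetic-data module that generates every
    input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    flexsurv,
    survival,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
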