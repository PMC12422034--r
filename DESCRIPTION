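Package: intecost
Title: Societal Cost-Minimisation Analysis of Integrated Chronic Care
Version: 0.1.0
Authors@R: person("INTE", "Costing Team", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Within-trial economic evaluation toolkit for comparing integrated
    and vertical (condition-specific) delivery of chronic care for HIV,
    hypertension and diabetes in low- and middle-income settings. Implements
    currency- and price-year-aware money arithmetic, purchasing-power-parity
    conversion to 2021 international dollars, capital annuitization, top-down
    facility cost allocation with bottom-up ingredients costing of medication
    and diagnostics, patient and household-caregiver time valuation, Welch
    comparisons of arm-level visit costs, national scale-up and budget-impact
    projection, deterministic sensitivity analyses, and a synthetic
    cluster-trial generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
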