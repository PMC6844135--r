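Package: costpaf
Title: Attributable Health Care Costs from Behavioural and Socioeconomic
    Risk Factors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the share of public health care expenditure
    attributable to health behaviours (smoking, alcohol, diet, physical
    inactivity) and socioeconomic position using survey cohorts linked to
    per-person sector costs. Fits sex- and sector-specific negative
    binomial cost models with a person-years offset over a stepped
    covariate ladder, computes factor-deleted counterfactual population
    attributable fractions (model-based standardization), converts PAF
    series into attributable and avoided dollars against annual sector
    budgets with CPI inflation, and provides sensitivity analyses
    (model-ladder bounds, high-cost-user exclusion with age-standardized
    cost ratios, inverse-probability-of-treatment weighting). Includes a
    synthetic multi-cycle survey cohort generator with enumerable ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    nnet,
    stats,
    utils,
    jsonlite,
    yaml,
    rlang
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
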