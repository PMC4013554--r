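Package: impactdm
Title: Discrete-State Markov Forecasting of Type 2 Diabetes Prevalence from
    Risk-Factor Trends
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements an age- and sex-stratified discrete-state Markov
    model that projects the prevalence of type 2 diabetes mellitus from
    exogenous population trajectories and linear obesity and smoking
    prevalence trends.  The living population of each sex by ten-year
    age-band stratum is partitioned every annual cycle into Healthy, Obese,
    Smoker and Diabetes compartments, resolving the obese-smoker overlap
    and removing attributable diabetes cases from exposure pools via
    Levin's population attributable risk.  Overall diabetes incidence is
    decomposed into incidence among the unexposed, scaled by relative
    risks for the exposed states, and propagated with competing-risk
    transitions (case fatality and background mortality).  Includes
    analysis-of-extremes uncertainty intervals, capped-obesity scenario
    analysis, a synthetic input-bundle generator, a stochastic
    microsimulation oracle for engine validation, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
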