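Package: smokehia
Title: Dynamic Health Impact Assessment of Tobacco-Control Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Multistate life-table health impact assessment of tobacco-control
    policies. Estimates never/current/former smoking prevalence from survey
    microdata with fractional-polynomial logistic smoothing, links smoking to
    disability through prevalence-odds inversion, derives net start/quit/restart
    transition probabilities that hold age-specific smoking prevalence
    stationary, projects the population thirty years forward under
    counterfactual scenarios by partial microsimulation (with an exact
    deterministic recursion as oracle), and reports life expectancy, healthy
    life years and unhealthy life years by the Sullivan and cohort methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
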