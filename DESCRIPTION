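Package: ssbtax
Title: Simulation of Sugar-Sweetened Beverage Tax Effects on Obesity and Costs in Brazil
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end policy model of ad valorem excise taxes on
    sugar-sweetened beverages (SSB) for the adult Brazilian population.
    Estimates own- and cross-price elasticities of beverage demand from
    household budget survey purchase data using survey-weighted log-log
    regressions with cluster-robust standard errors; converts elasticities
    and baseline 24-h recall beverage intake into per-person caloric
    changes under 20% and 30% tax scenarios; corrects self-reported weight
    and height against a measured reference survey via sex-specific
    quantile-difference cubic splines; propagates caloric changes through
    the adult dynamic energy-balance model of Hall and colleagues to
    obtain 10-year body-weight and obesity-prevalence trajectories; and
    translates prevalence reductions into obesity cases averted and
    discounted healthcare cost savings with a no-benefit lag. A seeded
    synthetic-data generator emulates the restricted POF/PNS microdata so
    the full pipeline is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    sandwich,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
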