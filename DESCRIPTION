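Package: dietopt
Title: Least-Cost Diet Optimization for Pregnancy Nutrition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Formulates and exactly solves the least-cost diet problem for
    pregnant women as an integer linear program: minimize daily food cost
    subject to per-trimester nutrient intake bounds (RNI 2017), food-group
    serving bounds with palatability limits on sugar, salt and oil
    (MDG 2010), and per-item serving caps. Includes supplement-scenario
    comparisons, binding-constraint and infeasibility diagnostics, day-menu
    assembly over five meal slots, dietary-recall adequacy summaries
    (percentage of a cohort achieving the RNI, macronutrient energy
    contributions, haemoglobin and BMI classification), and seeded synthetic
    generators for food databases, recall records and optimization instances
    with known optima.
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
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr
Config/testthat/edition: 3
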