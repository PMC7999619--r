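Package: porkopt
Title: Bio-Economic and Environmental Assessment of Feed-Efficiency-Tailored Pig Diets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates fattening pigs from two lines divergently selected for
    residual feed intake, formulates line-tailored diets under nutritional
    constraints for least-cost, least-environmental-score and joint
    cost-environment objectives (exact linear-programming and evolutionary
    solvers), and assesses every line-by-diet scenario with an individual
    trait-based bio-economic profit model and a simplified cradle-to-farm-gate
    life cycle assessment. Includes a seeded synthetic-data generator for
    ingredient libraries, pig populations and study configuration, a trade-off
    sweep over the cost-environment weighting, zero-profit market sensitivity,
    and line-comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
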