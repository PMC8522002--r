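Package: markovce
Title: Markov Cohort Cost-Effectiveness Analysis for Ex-Ante Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A Markov cohort state-transition engine for ex-ante
    cost-effectiveness evaluation of interventions, in the style of the
    MAFEIP decision-support framework. Models are declared as states with
    per-arm transition matrices, costs (single, periodic, indirect) and
    per-state effects; the engine propagates a cohort distribution through
    cycles, accrues expected costs and effects, computes incremental
    cost-effectiveness ratios, classifies results on the cost-effectiveness
    plane, and applies willingness-to-pay decision rules. Includes
    transition-probability estimation from count tables, declarative
    scenario analysis and one-way parameter sweeps, a random model
    generator for property testing, YAML/CSV model serialization, ggplot2
    visualizations, and a worked smart-city transport case study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
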