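Package: quitcea
Title: Cost-Effectiveness and Value-of-Information Analysis of Smoking
    Cessation Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A Markov cohort model of one quit attempt by a cohort of UK
    smokers, used to compare fourteen smoking-cessation interventions
    (nicotine replacement therapy, bupropion, varenicline, e-cigarettes,
    and combinations) on lifetime discounted costs and quality-adjusted
    life years, accounting for depression and self-harm attributable to
    the interventions. Provides probabilistic sensitivity analysis driven
    by a seeded synthetic-parameter generator, incremental and dominance
    analysis with extended dominance, cost-effectiveness acceptability
    curves and rank-o-grams, and expected value of (partial) perfect
    information via regression metamodelling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    mgcv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
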