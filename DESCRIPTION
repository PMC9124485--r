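Package: winterq
Title: Activity-Controlled Metabolic Rate and Winter Dormancy Analysis for Fishes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether overwintering fishes depress their
    metabolism actively (metabolic rate depression) or merely become inactive
    while standard metabolic rate (SMR) slows passively with cooling.
    Implements intermittent-closed respirometry trace reduction (closed-period
    slope fitting, blank correction, mass-specific scaling), behavioural
    reduction of tracked movement, sheltering, vigilance and feeding records,
    SMR estimation at each temperature by exponential extrapolation of oxygen
    uptake to zero spontaneous activity (individual and pooled), lowest-20
    subsets and activity-controlled band means, Q10 thermal sensitivity with
    a 3.5 threshold for inferring metabolic rate depression, Arrhenius
    breakpoint detection, and dormancy threshold detection from cold
    behavioural steady states. A synthetic-data generator with known ground
    truth (Arrhenius SMR, exponential activity-metabolism coupling, logistic
    cold damping of diel activity, respirometer oxygen dynamics) makes every
    stage testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
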