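Package: adaptrand
Title: Covariate-Adaptive Dynamic Randomization for Clinical Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A sequential treatment-allocation engine for randomized
    controlled trials that recalculates per-group probability boundaries
    for every arriving participant from a weighted sum of signed squared
    imbalances measured simultaneously at the overall level, within each
    stratification variable and within the full stratum
    cross-classification.  Supports two or more treatment groups, unequal
    allocation ratios, arbitrary discrete stratification schemes, durable
    CSV allocation logs with full replay, YAML trial configuration files,
    and a seeded Monte Carlo simulator that summarizes final and interim
    allocation splits, within-level imbalances, boundary distributions and
    same-group run lengths over replicated synthetic trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
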