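Package: benthme
Title: Benthic Biomass Analysis with Minimum-Effects Hypothesis Tests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Statistical pipeline for nearshore benthic biomass surveys of
    the kind used to monitor gray whale feeding grounds: a calibrated
    zero-inflated lognormal survey simulator, mixed-model analysis of
    covariance on ln(X+1) biomass with Satterthwaite denominator degrees of
    freedom, minimum-effects interval hypothesis tests on noncentral F
    distributions with post hoc power, Bray-Curtis / NMDS / permutational
    MANOVA community analysis with Holm-adjusted pairwise comparisons, and
    descriptive biomass threshold and dominance summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    vegan,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
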