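Package: metstab
Title: AMMI and GGE Biplot Stability Analysis for Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Genotype-by-environment stability analysis for balanced
    multi-environment trials laid out as randomised complete block designs.
    Implements the additive main effects and multiplicative interaction
    (AMMI) model with Gollob degrees of freedom for the interaction
    principal component axes, partitioning of the interaction sum of
    squares into signal and noise, the modified AMMI stability index
    (MASI) and the rank-based simultaneous selection index (SSI),
    rain-water-use efficiency as a derived trait, and the four standard
    GGE biplot analyses (which-won-where, mean versus stability,
    discriminativeness versus representativeness, ideal-genotype ranking)
    computed as plain tables from the environment-centered SVD. A
    synthetic trial generator with known additive and multiplicative
    structure supports ground-truth testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    grDevices,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
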