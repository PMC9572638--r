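Package: metstab
Title: Multi-Environment Forage Trial Analysis: Drought Indices, AMMI
    Stability and Quantitative Genetic Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for staged-harvest multi-environment forage
    trials under water-stress regimes: balanced factorial ANOVA with LSD
    mean separation, variance-component estimates of genotypic and
    phenotypic coefficients of variation and broad-sense heritability,
    stress tolerance index (STI) and water-use efficiency (WUE) screening
    with hierarchical tolerance classification, AMMI decomposition of
    genotype-by-environment interaction with ASV and yield stability
    index (YSI) ranking, and annual dry-matter and crude-protein yield
    accumulation. Includes a synthetic trial generator with known
    ground-truth effects for parameter-recovery testing, and a packaged
    transcription of a published 84-genotype Napier grass annual-yield
    table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ape,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
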