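Package: eratrend
Title: Breeding Progress, Plasticity, Selection Signals and Environmental
    Sensitivity in Era Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidy toolkit for analysing multi-environment era trials of
    crop cultivars released over several breeding decades. Computes
    per-environment best linear unbiased estimates (BLUEs) from plot data,
    absolute and relative breeding progress with trend classification, a
    range/mean phenotypic plasticity index and its progress over release
    years, a polygenic selection-signal test combining ridge-regression
    marker effects with allele-frequency change under a permutation null,
    a thermal-time windowed sensitivity scan of yield components to
    short-term weather, and anatomical maximum stomatal conductance from
    stomatal counts and dimensions. Ships a synthetic-data generator with
    known ground truth for every pipeline stage.
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
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
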