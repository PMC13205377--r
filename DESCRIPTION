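Package: pigtme
Title: Trait Measurement Error Analysis for Depth-Camera Pig Body Weight
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying trait measurement
    error (TME) in computer-vision-derived pig body weight. Generates synthetic
    genotype, phenotype and top-view depth-video data with configurable random
    or genetically structured measurement error; segments depth frames by
    adaptive hue thresholding and extracts biometric features (dorsal length,
    abdominal width, height, volume); predicts body weight with ordinary least
    squares and random-forest regressions; estimates genomic heritability by
    spectral REML under the GBLUP model and runs single-marker mixed-model
    genome-wide association scans with null variance components held fixed; and
    assembles per-time-point reports comparing scale-based body weight,
    image-based body weight and their absolute difference, including top-k
    marker agreement statistics.
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
    png,
    purrr,
    randomForest,
    readr,
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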