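Package: vtsubstrate
Title: Localizing Ventricular Tachycardia Ablation Targets from Substrate Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Multi-domain feature extraction from intracardiac electrograms
    (functional, spatial, spectral and time-frequency features including a
    Smoothed Pseudo Wigner-Ville Distribution), distance-based labeling of
    potential ablation targets around ventricular-tachycardia critical sites,
    mixed-effects logistic association screening with Bonferroni and
    variance-inflation-factor pruning, and a leakage-aware machine-learning
    classification protocol (grouped splits, repeated grouped cross-validation,
    class undersampling, random-forest importance pruning and distance
    sensitivity analysis). Includes a seeded synthetic electroanatomical-study
    generator so the full pipeline can be exercised and tested without access
    to clinical mapping-system exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    pROC,
    purrr,
    randomForest,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
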