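Package: gutnk
Title: Composite Gut Dysbiosis and NK-Cell Exhaustion Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds composite, percentile-binned scores linking gut microbiota
    dysbiosis to natural killer (NK) cell exhaustion in cervical cancer.
    Provides genus-level alpha-diversity metrics (Shannon, Simpson, Pielou
    evenness, Simpson evenness, Strong dominance), centered log-ratio (CLR)
    transformation and taxonomic ratio panels, Z-score/percentile-bin
    composite scoring against a healthy-donor reference, fixed-coefficient
    logistic risk models with odds ratios, ROC/Youden cutoff utilities,
    Kaplan-Meier and log-rank survival stratification, and a seeded synthetic
    cohort generator that emulates the statistical structure the analysis
    assumes. All user-facing functions take data frames and return tibbles.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
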