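Package: dietscore
Title: Personalized Energy-Adjusted Diet Quality Scoring from 24-Hour Nutrient Intakes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a personalized, energy-adjusted diet quality score (DQS)
    over daily nutrient intake totals. Sixteen index nutrients are scored with
    piecewise-linear functions anchored on age- and gender-specific healthy
    ranges (Dietary Reference Intakes, Acceptable Macronutrient Distribution
    Ranges, and World Health Organization limits for nutrients to moderate);
    the unweighted mean of the nutrient subscores is multiplied by an energy
    score built around the Institute of Medicine estimated energy requirement.
    Also provides the reliability and agreement statistics used to validate
    such scores (Cronbach's alpha with Feldt confidence intervals,
    Bland-Altman limits of agreement, quantile stratification with
    Kruskal-Wallis comparison, principal-component variance decomposition), a
    seeded synthetic-diet generator with controllable diet quality for
    end-to-end testing, delimited-text intake and score readers and writers
    with column mapping, and a command-line interface.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
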