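Package: dietscreen
Title: Diet-Quality Screening, FFQ Nutrient-Coverage Evaluation and
    Personalised Dietary Advice
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for evaluating and applying a short
    food-frequency-questionnaire (FFQ) based diet-screening tool in a
    sports-medicine setting.  Computes per-food contributions to the level
    (MOM1) and between-person variance (MOM2) of nutrient intake from
    repeated 24-h dietary recalls and decides whether an FFQ's item set
    sufficiently covers each nutrient; screens implausible energy intake
    with the Goldberg cutoff and Schofield basal-metabolic-rate equations;
    scores short-FFQ responses into the 16-component Dutch Healthy Diet
    2015 index plus micronutrient and protein compliance scores;
    classifies blood micronutrient panels against sex-specific reference
    ranges; generates rule-based personalised dietary advice from the
    combination of blood status and diet quality; and compares
    baseline/follow-up diet quality with paired tests.  A synthetic-data
    module generates every pipeline input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
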