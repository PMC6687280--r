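Package: streamstress
Title: Multi-Stressor Analysis of Stream Macroinvertebrate Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantifying single and combined effects of
    agricultural stressors (pesticide toxicity, nutrient enrichment, habitat
    alteration) on stream macroinvertebrate communities. Computes pesticide
    toxic units from concentrations and Daphnia magna LC50 values, the SPEAR
    pesticides and BMWP family-score biotic indices, fits candidate linear
    mixed models with AR(1) within-site correlation selected and averaged by
    AICc, classifies stressor interactions against the additive expectation,
    and partitions community-composition variance among stressor sets with
    Hellinger-transformed (partial) redundancy analysis, adjusted R-squared
    and permutation tests. Includes a synthetic-data generator emulating a
    repeated-measures biomonitoring design so every stage is testable against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
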