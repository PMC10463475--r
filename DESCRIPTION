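Package: inequidec
Title: Decomposition of Socioeconomic Inequality in Binary Health Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for measuring and decomposing wealth-related inequality in
    binary health outcomes from weighted survey microdata. Implements the
    asset-based wealth index (principal component analysis of standardized
    asset indicators with weighted quintiles), weighted fractional ranks, the
    Kakwani concentration index and concentration curve, crude and adjusted
    odds ratios from weighted logistic regression, and the regression-based
    decomposition of the concentration index into covariate contributions.
    Includes a synthetic survey-microdata generator with known ground truth
    so the whole pipeline can be exercised and validated without restricted
    survey files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
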