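Package: dietcost
Title: Least-Cost Nutritious Diet Modeling with Wild Foods and
    Micronutrient Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Linear-programming models of least-cost, nutritionally
    adequate weekly diets for women of reproductive age and young
    children, built from local market price surveys, food composition
    tables, and culturally derived intake-frequency constraints.
    Includes bioavailability conversions for calcium, iron and
    beta-carotene, intervention scenario ladders (wild vegetables, wild
    fruits, micronutrient powder), nutrient-adequacy profiling,
    wealth-group affordability analysis, and a fully synthetic data
    generator for two-season, multi-village market surveys with
    engineered nutrient gaps of known magnitude.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    boot,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
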