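Package: contextchoice
Title: Context-Dependent Choice and Valuation in Consumer Review Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying context-dependent choice and valuation in
    large consumer review streams. Reconstructs geographically and
    categorically defined choice sets from timestamped review data (category
    inference from review text, density-based spatial clustering of review
    coordinates), maintains time-indexed half-star displayed ratings, derives
    context-effect statistics (ratings-maximizing choice, distractor/IIA
    analysis, rating deviations, expectation ratings), and fits per-user
    mixed-effects regressions. Includes a fully parameterized synthetic-world
    generator built on a divisive-normalization choice model and a
    prediction-error rating model, so every pipeline stage can be validated
    against ground truth without proprietary data.
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
    lme4,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
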