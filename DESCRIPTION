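Package: aggexpo
Title: Aggregate Oral Chemical Exposure Across Childhood Lifestages
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes deterministic average daily doses (ADD, mg/kg-day) of a
    chemical ingested from ten oral media (soil, dust, water, breastmilk and
    six food groups) for the eleven Exposure Factors Handbook age groups,
    regroups them by time-weighted averaging into seven childhood and adult
    lifestages, derives lifetime average daily doses (LADD) and percent media
    contributions, and renders the five stacked-bar graph families used in
    children's aggregate exposure assessment. Includes non-detect (limit of
    detection) substitution policies for summarising censored concentration
    data, packaged case-example concentration tables, a synthetic-data
    generator, and a deterministic run pipeline with a command-line entry
    point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    yaml,
    withr,
    digest,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
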