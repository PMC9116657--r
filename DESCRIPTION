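Package: cremains
Title: Quantitative Analysis of Commingled Cremated Bone Deposits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative osteoarchaeology of cremation sites
    recorded on an excavation grid: a long-format data model for per-square,
    per-stratum cremated-bone weight records; fragmentation and
    cranial/post-cranial indices; grid density maps, transects, hotspot
    ranking and cluster statistics; a demographic weight-budget solver that
    estimates the minimum number of cremated individuals under primary and
    residual depositional hypotheses; and a seeded generator of synthetic
    deposits for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
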