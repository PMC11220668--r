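Package: antscale
Title: Activity Regulation and Metabolic Scaling in Ant Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse activity regulation in social-insect colonies
    from per-worker trajectories: spatial proximity networks and their
    time-averaged interaction counts, grid-based spanned area, active/inactive
    classification, allometric (power-law) and linear fits with t-based
    confidence intervals, a reverse-social-contagion model linking interaction
    scaling to the number of active workers, and a Cobb-Douglas production
    function linking activity to whole-colony metabolic rate. Includes a
    synthetic-data generator (summary-level and trajectory-level) emulating
    clustered spatial occupancy and the assumed scaling structure, so the full
    pipeline is testable without tracked video data.
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
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
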