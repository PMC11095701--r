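Package: carecontact
Title: Contact Networks and Quality-Improvement Reports from Care-Home
    Wearable Proximity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Turns Bluetooth Low Energy (BLE) proximity sighting streams
    collected by wearables in residential care homes into interaction
    episodes, weighted undirected social networks with resident / staff /
    agency role attribution, standard social-network-analysis metrics,
    modularity-based subcommunity partitions, and the summary tables used
    for quality-improvement feedback (interaction strength and duration,
    centrality by role, long-interaction role contingency, unique-partner
    counts, hour-of-day and location profiles). Includes a ground-truthed
    synthetic care-home simulator so the whole pipeline can be exercised
    and validated without access to real resident data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xml2
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
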