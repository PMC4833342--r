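Package: srcscape
Title: Land-Use Simulation and Ecosystem-Service Assessment for Short
    Rotation Coppice Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Couples a spatially explicit economic land-use simulation
    (profit-maximizing per-pixel farmers choosing between short rotation
    coppice, annual crops and fallow, interacting through endogenous
    wood-chip and crop markets) with simplified ecosystem-service and
    biodiversity assessments (carbon storage, phosphorus export and
    retention with D8 flow routing, USLE-based sediment export, and a
    GLOBIO-style multiplicative mean-species-abundance model) and an
    ecosystem-service bundle analysis (k-means clustering, moving-window
    landscape composition, VIF screening and backward-stepwise logistic
    regression).  Ships a seeded synthetic-landscape generator so the whole
    pipeline is testable end to end without regional geodata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
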