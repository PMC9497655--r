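Package: metalchain
Title: Soil-Food-Chain Heavy-Metal Contamination and Dietary Risk Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for paired soil-crop heavy-metal surveys
    (Cd, Hg, As, Pb, Cr in rice, maize and cabbage): geo-accumulation index
    with a seven-class contamination scheme, Hakanson single-metal and
    combined potential ecological risk indices, EPA-style dietary exposure
    and risk (estimated daily intake, hazard quotients, carcinogenic risk),
    and a log-linear soil-to-crop transfer regression for cadmium driven by
    soil pH and soil concentration, with outlier screening and
    back-transformed prediction. Ships a synthetic-data generator that
    emulates the marginal concentration distributions and the soil-crop
    cadmium link of a karst farmland survey so the whole chain can be
    exercised and tested without access to raw field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
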