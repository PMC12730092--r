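Package: chamberflux
Title: Respiration-Chamber Methane Flux and Nutrient Balance for Dairy Cattle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes enteric methane emissions from open-circuit respiration
    chamber sensor streams (humidity and STP ventilation corrections, analyzer
    calibration and drift back-correction, chamber gas-recovery correction,
    multiplexed sampling-cycle demultiplexing, event-driven gap filling, and
    daily totals) and per-cow nutrient balances for lactating dairy cattle
    (fat- and energy-corrected milk, internal-marker digestibility,
    creatinine-based urine volume, nitrogen partition and nitrogen-use
    efficiency, gross-to-metabolizable energy partition, and methane yield and
    intensity metrics). Includes a synthetic-data generator for chamber sensor
    streams and animal records with known ground truth so the whole chain can
    be verified without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    lubridate,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    jsonlite
Config/testthat/edition: 3
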