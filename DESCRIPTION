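Package: rfidforage
Title: Foraging Bout Extraction and Reward-Specialization Analysis for
    RFID-Tracked Bee Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Processes raw RFID antenna-read streams from a two-chamber
    (nectar/pollen) foraging setup into directed chamber transits, chamber
    visits, and scored foraging bouts, then computes per-forager reward
    specialization at daily and lifetime timescales, a transition-based
    constancy index, colony-level daily time series, and foraging-effort
    concentration (Lorenz) statistics.  Includes a generative colony
    simulator with planted ground truth so every pipeline stage can be
    validated end to end, and a small hypothesis-testing battery (exact
    signed-rank, chi-square goodness of fit, paired t, least-squares
    regression with configurable null slope, nested F) used to analyse
    pipeline outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
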