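Package: pinscreen
Title: Analysis of Pinned Colony-Array Chemogenomic Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring drug-gene interactions from pinned colony-array
    (384/1536 density) chemogenomic screens of mutant libraries. Implements
    intra-plate 70th-percentile size normalization, positional artifact
    correction (row, column, neighborhood, competition), exclusion of
    replicate-discordant jackpot colonies, a standard-deviation-corrected
    genetic-interaction score with two-SD significance calling and
    Benjamini-Hochberg FDR control, cross-background suppressor
    stratification, and a seeded synthetic screen generator with planted
    ground truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
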