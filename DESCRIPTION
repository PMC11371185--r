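Package: meioscope
Title: Crossover Patterning Analysis for Meiotic Cytology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of crossover patterning from per-meiocyte cytology
    tables: configuration-based minimum chiasma scoring (ring/rod/univalent),
    class I/II crossover partition from HEI10-labelled chiasmata, per-bivalent
    focus-count distributions tested against a constructed Poisson null under
    two explicit binning policies, normalized inter-focus spacing summaries,
    immunofluorescence intensity normalization, and Games-Howell multiple
    comparisons. Includes a dosage-aware synthetic meiocyte simulator placing
    class I crossovers by a stationary gamma-renewal process (interference
    strength nu) with an independent Poisson overlay of class II crossovers,
    obligate-crossover mechanisms, and a detection layer, used for parameter
    recovery and test calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
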