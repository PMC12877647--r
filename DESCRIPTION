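Package: spscore
Title: Structural Pathogenicity Scoring of Ion-Channel Missense Variants
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Structure-based binary classification of missense-variant
    pathogenicity for the cardiac hERG (KCNH2) potassium channel and other
    ion channels with a resolved structure. Five per-variant metrics --
    residue size change, hydrophobicity change, formal-charge change,
    rotamer-weighted steric-clash severity, and contacts with known
    pathogenic hotspot positions -- are aggregated by a fixed scaling
    equation into a Structural Pathogenicity Score (SPS) on a 1-5 grid in
    0.25 steps, with scores at or above 3.25 flagged as high pathogenic
    risk. Includes batch scoring of variant tables, ACMG-based threshold
    calibration, external-predictor concordance tabulation, and
    deterministic synthetic-structure fixtures for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
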