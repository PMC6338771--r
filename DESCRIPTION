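Package: oligodimer
Title: Primer-Dimer Scoring, ROC-Based Thresholds and Dimer-Aware Multiplex Design
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts extensible primer-dimer formation from nearest-neighbour
    DNA thermodynamics. Scores every sliding alignment of the three possible
    primer-primer pairings with a 3'-anchored prefix-minimum free-energy value
    plus empirically calibrated penalties and bonuses, optionally adjusted for
    primer length and G+C content. Labeled primer sets are evaluated with ROC
    curves to yield an AUC and a dimer-free discrimination threshold; bonus
    and penalty magnitudes can be re-derived by grid search; and a greedy
    builder assembles multiplex PCR primer pools whose pairwise interactions
    all clear the dimer-free cutoff. Includes a synthetic data generator that
    plants 3'-complementary dimer motifs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
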