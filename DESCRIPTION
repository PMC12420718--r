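Package: descorecard
Title: Scorecard Classification and Synthesis of Multi-Condition
    Differential Expression Results
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesizes differential-expression results across many
    experimental conditions with a "scorecard": a two-threshold,
    significance-filtered classification of genes into lettered regions of
    interest on a pairwise log2 fold-change plane. Provides readers for
    tabular per-comparison results, derivation of pairwise contrasts from
    expression tables, the region classifier itself, collection-level
    aggregation (region count matrices, gene occurrence, exclusive genes,
    difference rankings, annotation keyword frequencies, longitudinal
    region tracking), JSON archives, CSV tables, machine-parseable logs,
    and ggplot2 figures (scorecard scatter, radial overview, paired bars,
    region heatmap). A seeded synthetic fixture generator plants genes in
    known regions so every analysis step can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
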