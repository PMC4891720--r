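Package: polyrun
Title: Homo-Repeat Detection and Null-Model Statistics for Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects homo-repeats (uninterrupted single-amino-acid runs) in
    protein sequence sets, computes the exact distribution of the longest run
    under an i.i.d. residue null model via a dynamic-programming recursion
    together with a closed-form approximation, and compares observed and
    expected repeat counts with a 10-fold significance rule. Also provides a
    contingency Z-score for disease association of repeat-bearing proteins,
    a seeded resampling test for repeat enrichment in protein target sets,
    interaction-partner summaries per repeat class, and a synthetic proteome
    generator (null sequences, spiked repeats, disease labels, interaction
    edges) with recorded ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
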