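Package: synlethscreen
Title: Expression-Profile Pre-Screening of Druggable Synthetic-Lethal
    Partners of p53
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Candidate screening pipeline for kinase genes that are
    potentially synthetic lethal to mutant p53, driven by gene-expression
    profiles. Samples are classified into functional-p53-mutant and
    non-mutant classes from TP53 mutation annotations; per-gene two-class
    t/F statistics with label-permutation p-values and Benjamini-Hochberg
    false-discovery rates identify genes over-expressed in the mutant
    class; directional and kinome filters plus cross-dataset consensus
    produce candidate tables; and a one-sided comparison of normalized
    -log(GI50) drug-sensitivity z-scores evaluates compounds that target
    the candidates. A seeded synthetic-data generator emulating the shape
    of NCI-60-style datasets makes every stage testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
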