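Package: strgain
Title: Repeat Tract Sizing and Somatic Instability Statistics from Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Sizes trinucleotide repeat tracts (such as the HTT exon 1 and
    ATXN3 exon 10 CAG tracts) from single-end amplicon sequencing reads by
    unique classification against a ladder of reference sequences differing
    only in repeat count, calls progenitor allele lengths from bimodal
    read-length distributions in non-expanding cell types, and computes
    somatic-instability statistics (ratio of somatic expansions, mean
    somatic length gain) together with cohort-level comparisons
    (one-way ANOVA with Holm-Sidak multiple comparisons, ratio paired
    t-test). Includes a PCR-stutter-aware amplicon read simulator with
    known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
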