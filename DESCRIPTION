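Package: phagehost
Title: Phage Host Prediction from Shared Genomic k-mers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the bacterial host genus and species of a bacteriophage
    from its genome sequence by counting 16-mers shared with a reference
    database of phages with annotated hosts. Implements a family of k-mer
    similarity statistics with Bonferroni-corrected z-score significance
    filtering, four host-selection criteria with coverage-based confidence
    tiers, Hobohm-1 redundancy clustering with host-balanced partitioning,
    cross-validation and bootstrap evaluation with nested parameter tuning,
    a genome-truncation robustness experiment, and a synthetic phage-corpus
    generator with planted host signatures for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
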