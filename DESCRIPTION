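Package: nsafdep
Title: Label-Free Spectral Counting Differential Expression with
    Abundance-Tiered Thresholds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for label-free quantitative proteomics based on spectral
    counting. Implements the normalized spectral abundance factor (NSAF),
    an abundance-tiered classifier for differentially expressed proteins
    that adapts p-value and fold-change cutoffs to each protein's spectral
    count tier, technical-replicate quality control based on the
    coefficient of variation of per-run protein totals, and
    presence/absence annotation of candidate proteins against a control
    proteome. A seeded spectral-count simulator with planted fold changes
    supports power and false-discovery assessment of the classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
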