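Package: granora
Title: Pathway Granularity Effects in Over-Representation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact hypergeometric over-representation analysis (ORA) with
    tools to study how pathway-database granularity shapes enrichment
    results. Provides a log-space hypergeometric tail engine, Bonferroni and
    Benjamini-Hochberg corrections, paired fine/coarse database comparisons
    that regenerate published EcoCyc-vs-KEGG p-value tables, a
    critical-subset-size solver (the minimum number of significant pathway
    genes needed to reach a fixed adjusted threshold), cross-database
    analogous-pathway matching by gene-set overlap, and a seeded generator
    of dual-granularity synthetic pathway annotations for end-to-end
    testing without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
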