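Package: ripscore
Title: RIP-Seq Enrichment Scoring and Label-Free Interactome Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying the RNA and protein partners of an
    RNA-binding protein from immunoprecipitation experiments. Implements a
    negative-binomial Wald test of IP-versus-input enrichment for RIP-seq
    count matrices with median-of-ratios normalization, a composite
    selection score (log2 fold change times minus log10 p, the "Vfactor")
    with a strict selection threshold, and a Perseus-style label-free
    AP-MS interactor workflow: peptide-evidence filtering, log2 LFQ
    transformation, valid-value filtering, down-shifted Gaussian
    imputation of missing-not-at-random values, and a permutation-FDR
    volcano with an s0-moderated test statistic. Also provides
    hypergeometric gene-set over-representation, set overlap statistics,
    western-blot densitometry fold-change testing, and seeded synthetic
    data generators with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    readxl,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    broom,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
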