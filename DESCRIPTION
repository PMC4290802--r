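Package: dpsnp
Title: Differentially Private Release of Top-K Disease-Associated SNPs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for releasing the K most disease-associated single-nucleotide
    polymorphisms (SNPs) from case-control genome-wide association data under
    epsilon-differential privacy. Implements the allelic test (Cochran-Armitage
    trend) chi-square statistic on 2x3 genotype contingency tables, an exact
    shortest-Hamming-distance score measuring how many single-individual
    genotype changes separate a table from the significance boundary (a score
    with sensitivity 1), and the Laplace and exponential release mechanisms
    built on either score. Includes a brute-force breadth-first-search oracle
    for the Hamming score, exhaustive sensitivity auditors, a synthetic
    case-control panel generator, and risk-utility sweep tooling for comparing
    mechanisms across privacy budgets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
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
    vctrs,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
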