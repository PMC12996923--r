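Package: methdev
Title: Genotype-Associated DNA Methylation Analysis Across Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for analysing genotype-associated
    differences in DNA methylation measured on beadchip arrays across a
    developmental time course. Covers sample and probe quality control,
    quantile normalisation, variable-probe selection, reference-based
    cell-type deconvolution with a reconstruction-error score, a weighted
    methylation pseudo-age score, probe-level differential methylation with
    genotype-by-age interaction testing, gene-level p-value aggregation via
    the Empirical Brown's method, consecutive-probe differentially
    methylated region calling, probe-density-adjusted functional enrichment
    with iterative conditional term selection, overlap testing against
    external region sets, and a kinetic enzyme-assay quantification helper.
    Includes a synthetic-data generator that emulates a two-genotype by
    five-age design with cell-type mixtures, batch effects and planted
    genotype effects, so that every stage is testable without downloads.
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
    limma,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
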