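Package: panmicro
Title: Genus-Level Tumor Tissue Microbiome Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analytics for genus-level microbial count tables
    recovered from tumor RNA-Seq, such as profiles of pancreatic ductal
    adenocarcinoma tissue. Provides quality-control filtering of low-read
    samples, relative-abundance transforms and taxonomic aggregation,
    Shannon alpha diversity, Bray-Curtis beta diversity,
    divergence-to-median community heterogeneity, permutational
    multivariate analysis of variance (PERMANOVA) implemented from first
    principles with exact enumeration for small designs, core-microbiota
    detection by abundance and prevalence thresholds, cross-dataset
    overlap partitions, pan-microbiome accumulation curves with Heaps-law
    fitting and extrapolation, and a Dirichlet-multinomial cohort
    simulator for calibration and power studies.
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
    vegan,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
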