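Package: isopqtl
Title: Protein Quantitative Trait Locus Mapping in Isolated Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for serum-proteome pQTL analysis in
    founder-population cohorts: Olink NPX phenotype quality control and
    inverse-normal transformation, linear mixed-model association with an
    empirical relatedness matrix, fixed-effect inverse-variance meta-analysis
    across cohorts, LD-aware peak extraction with approximate conditional and
    joint (COJO-style) multi-signal selection, allele-frequency drift and
    novelty annotation against a cosmopolitan reference, Wakefield
    approximate-Bayes-factor colocalization, and two-sample Mendelian
    randomization of protein levels on complex traits. Includes a synthetic
    cohort generator (Balding-Nichols drift, Markov-chain LD haplotypes,
    sibship relatedness, planted cis/trans effects and LOD censoring) so the
    whole pipeline is testable without access restrictions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
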