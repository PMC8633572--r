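Package: xomap
Title: Crossover Detection and Recombination Landscapes in Selfing Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects meiotic crossovers from SNP-array genotypes of selfed
    F3 families using a conservative three-marker validation rule, masks
    markers that are uninformative (homozygous) in each family's parental F2,
    converts interval recombination fractions into Kosambi centiMorgans and
    genetic-map lengths, partitions recombination into distal, interstitial
    and pericentromeric zones and fixed-fraction physical bins, and compares
    populations with nonparametric tests. Includes a forward simulator of the
    F1-F2-F3 selfing design (Poisson crossovers with a configurable distally
    skewed density, genotyping error and missingness, full truth tracking)
    for validating the detection pipeline.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
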