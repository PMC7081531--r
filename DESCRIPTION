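Package: triocall
Title: Genotype Calling and Parentage Assignment for Triploid Offspring
    from SNP Array Allele Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls allele dosages for triploid (and diploid) individuals from
    SNP-array allele-signal contrasts by fitting univariate finite normal
    mixture models with equal- and heterogeneous-variance structures via a
    MAP-EM algorithm, selecting the cluster count by the integrated complete
    likelihood (ICL). Clusters are labelled through reference contrast means,
    uncertain calls are set missing, and per-marker quality statistics
    (delta-ICL, call rate) support filtering. Downstream tools assign diploid
    parents to triploid offspring by Mendelian exclusion ratios, predict
    parental sex from mother-specific exclusions, and map maternal
    recombination along chromosomes from informative trios, in the spirit of
    gene-centromere mapping. A pedigree-aware simulator of allele signals for
    pressure-shock induced triploids (second-polar-body retention) makes every
    stage testable without proprietary array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
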