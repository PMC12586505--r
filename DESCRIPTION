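Package: neandilute
Title: Genetic Dilution of a Small Resident Population by Recurrent Immigration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analytical and stochastic tools for the continent-island style
    dilution of a small resident hominin population (Neanderthal tribes) by
    recurrent small-scale immigration from a demographically unbounded source
    population (Homo sapiens). Implements the mean-field demographic rate
    model and its closed-form dimensionless trajectory, the three-genotype
    (resident homozygote, immigrant homozygote, heterozygote) dynamics within
    a stationary population, the immigration-cycle recursion with its
    allele-frequency equivalence to the classical continent-island model,
    dilution-time calculators, binomial/multinomial finite-tribe noise
    statistics (a genetic-drift proxy), multi-locus carrier statistics, and a
    forward-time Monte Carlo tribe-ensemble simulator that serves as an
    independent check on every closed form.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
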