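Package: passengr
Title: Passenger Mutation Dynamics During Tumor Clonal Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic theory and simulation of neutral (passenger) mutation
    accumulation in an exponentially expanding cancer cell population modeled
    as a supercritical multi-type birth-death branching process with
    infinite-allele mutation. Provides closed-form results for fixation
    probabilities and frequency distributions of successive surviving
    mutations, likelihoods of the six phylogenies of the first three surviving
    mutations, maximum-likelihood estimates of tumor size at a mutation's
    origin, and expected numbers of clonal and subclonal mutations. Includes
    an exact clone-level Gillespie simulator for validation, and a fitting
    pipeline that estimates the death-birth ratio from the cumulative variant
    allele fraction spectrum of tumor sequencing data, with a synthetic
    mutation-table generator for diploid tumors read at finite depth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    knitr
Config/testthat/edition: 3
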