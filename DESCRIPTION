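Package: admixpaint
Title: Haplotype Painting and Admixture Source Decomposition for Recently
    Admixed Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to decompose the ancestry of recently admixed individuals
    into contributions from closely related source populations and to time
    that admixture. Implements a Li & Stephens haplotype-copying hidden
    Markov model ("chromosome painting") with EM estimation of the switch
    and mismatch rates, a Bayesian mixture decomposition of per-individual
    copying vectors into candidate source populations by Markov chain Monte
    Carlo with a sparsity prior on the number of contributing sources, and
    admixture timing from diploid local-ancestry calls summarised as ternary
    genome fractions compared against closed-form pedigree expectations.
    Includes a synthetic-cohort generator (Balding-Nichols differentiated
    sources, explicit pedigrees with Poisson recombination, injectable
    phasing switch errors) with writers for phased VCF, recombination maps
    and truth tracts, plus an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    parallel,
    Rcpp,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
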