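Package: lfgsim
Title: Recombination and Adaptation on Fitness Landscapes with Low-Fitness Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the effect of bacterial recombination (transformation) on the
    rate of adaptation across multilocus fitness landscapes whose mutational
    paths are obstructed by low-fitness genotypes (LFGs). Provides construction,
    enumeration and symmetry classification of LFG fitness topographies; an
    infinite-population mutation-selection-recombination ODE model with
    fixation-time and linkage-disequilibrium measurements and a two-locus
    critical recombination rate; a finite-population Moran-type stochastic
    simulator (exact Gillespie algorithm with optional tau-leaping); and
    screening utilities that aggregate the recombination effect T_fix over
    topographies and parameter grids, including a physiological-epistasis
    regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
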