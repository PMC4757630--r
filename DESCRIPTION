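Package: foundertrace
Title: Phylogeographic Founder Analysis of mtDNA and Y-STR Variation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for tracing prehistoric migrations from a source region
    into a sink region using mitochondrial HVS-I haplotypes and Y-chromosome
    STR profiles.  Builds reduced-median and median-joining haplotype
    networks with iterative STR reweighting, identifies founder clusters
    under f1/f2 criteria, dates them with the rho statistic and Saillard
    standard errors using star-equivalent effective sample sizes, runs a
    Bayesian migration-time scan and fixed-window partition, calibrates
    Y-STR mutation rates from clades of known age, screens candidate
    dispersal markers against a five-point phylogeographic criteria test,
    and post-processes Bayesian skyline trajectories into expansion
    increments.  A two-deme coalescent-style simulator with known migration
    history supports parameter-recovery validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    ape,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
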