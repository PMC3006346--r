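Package: probmsc
Title: Polarized Site Patterns and Multispecies-Coalescent Inference for
    Multilocus Elephantid Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for nuclear multilocus analysis of elephantid
    speciation: readers for multilocus sequential PHYLIP alignments and
    tab-separated divergent-site tables, outgroup polarization and
    recurrent-mutation filtering, normalized pairwise divergence and
    heterozygosity with relative-rate tests, seven-class polarized
    site-pattern spectra and incomplete-lineage-sorting ratio tests,
    weighted delete-one-block jackknife standard errors, Neighbor-Joining
    phylogenies with site-bootstrap support, a structured-coalescent
    simulator of multilocus data under a five-taxon species tree (with an
    ancient-DNA damage channel for the outgroup), and a
    composite-likelihood estimator of split times and population sizes in
    mutation units.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
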