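Package: polyrep
Title: Comparative Repeat Abundance Analysis for Allopolyploid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying the inheritance of repetitive DNA after
    allopolyploidy from low-coverage shotgun reads. Simulates parental and
    tetraploid repeatomes with known ground truth, quality-filters and
    subsamples reads to a fixed genome proportion, clusters pooled
    species-tagged reads into repeat clusters through a k-mer-seeded
    similarity graph with community detection, filters contaminant and
    species-specific clusters, and tests the additivity of repeat
    abundances in the tetraploid: expected cluster sizes as the sum of
    parental abundances, cumulative deviation curves, log-log regressions
    of tetraploid on parental cluster size, and an F-test for equality of
    the two parental regression slopes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    data.table,
    igraph,
    jsonlite,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    grDevices,
    graphics,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
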