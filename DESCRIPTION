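Package: riverscape
Title: Riverscape Genomics of Fragmented Dendritic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing the genetic consequences of habitat
    fragmentation in dendritic river networks. Builds network-aware spatial
    predictors (river distance, in-stream barrier counts, catchment
    membership), decomposes pairwise FST into additive non-negative
    stream-section contributions (StreamTree), attributes differentiation to
    barriers, stream hierarchy and environment by multiple matrix regression
    with randomization (MMRR), estimates diversity and linkage-disequilibrium
    effective population size, and runs forward-time stepping-stone
    fragmentation simulations that measure how quickly drift generates
    differentiation after barriers sever migration. A synthetic-data module
    generates complete riverscape studies with recorded ground truth so the
    whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ape,
    igraph,
    pracma,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
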