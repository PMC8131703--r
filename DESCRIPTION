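Package: rtcompart
Title: Replication Timing and Chromatin Compartmentalisation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint analysis of Repli-seq replication-timing profiles and Hi-C
    chromatin compartmentalisation across genotypes. Computes log2(early/late)
    replication-timing scores from binned fraction counts, their distribution
    shape (Gaussian-mixture bimodality), replica correlation and hierarchical
    clustering, and between-condition timing-change classification. On the Hi-C
    side it provides iterative-correction matrix balancing, distance-decay
    scaling curves, observed/expected maps, A/B compartment eigenvectors,
    track-conditioned saddle plots with corner compartment-strength statistics,
    distance-stratified strength curves, differential maps and saddles against
    a reference genotype, and cross-sample PCA of compartment profiles. A
    block-model synthetic-data generator plants known replication-timing
    structure and dose-tunable compartment strength so the whole pipeline is
    testable end to end against closed-form oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    mclust,
    yaml,
    ape,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
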