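Package: quartetscan
Title: Quartet-Support Genome Scans for Gene Tree Discordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics and genome scans for gene tree-species tree discordance
    under the multispecies coalescent (MSC). Computes quadripartition quartet
    support (QQS), branch quartet support (BQS), clade monophyly and uniting
    branch lengths, and quartet scores of candidate species trees from
    collections of per-locus gene trees; runs a sliding-window Z-test with
    Benjamini-Hochberg correction to flag chromosomal regions whose quartet
    support is inconsistent with genome-wide MSC expectations; post-processes
    coalescent-HMM site posteriors into windowed topology-support fractions and
    MSC-admissibility checks; and simulates MSC locus trees along a genome with
    a planted discordance-free block, gene-tree error, and taxon dropout, plus
    Wright-Fisher polymorphism-persistence simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
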