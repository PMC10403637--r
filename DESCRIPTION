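Package: haplomine
Title: Top-Down Closed-Pattern Mining of Rare Haplotypes in Phased
    Case-Control Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers rare, possibly noncontiguous haplotype patterns shared
    by case chromosomes in phased genotype data by iterated pairwise (or
    sigma-wise) overlap of chromosomes, a top-down closed-pattern mining
    strategy.  Includes the generalized triangular-array mapping from a flat
    work-item index to a chromosome combination for partitioned computation,
    Fisher's exact and conditional (haplotype-restricted) association tests,
    Cox proportional-hazards and logistic dosage models with likelihood-ratio
    tests, stepwise forward selection, linkage-disequilibrium metrics, a
    stratified permutation null for estimating false-positive replication
    rates, Gini-based haplotype reduction, and a two-phase analysis pipeline
    (common-haplotype discovery followed by conditional rare-subtype
    discovery).  A coalescent-free founder-mosaic simulator generates phased
    case-control cohorts with embedded risk haplotypes so that every stage is
    testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    rpart,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
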