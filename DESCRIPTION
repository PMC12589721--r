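Package: boreff
Title: Boron-Efficiency Phenomics and Association Genetics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of boron (B) efficiency across a diverse
    panel of naturally inbred plant accessions phenotyped under B-deficient
    and B-sufficient conditions. Computes deficiency:sufficiency trait
    ratios and relative growth rates from replicated shoot trajectories,
    derives composite shoot and root B-efficiency indices (BEI) with
    rank-percentile classification, profiles phenotypic response patterns
    by k-means clustering of standardised trait ratios, builds SNP-based
    neighbour-joining trees with Fitch parsimony scoring and clade
    enrichment tests, and runs a single-marker genome-wide association
    scan with Bonferroni control, LD-decay-padded QTL windows, an
    efficiency-allele ledger, allelic ANOVAs and protein-haplotype
    contrasts. Includes a synthetic-data generator with planted
    pleiotropic QTL effects and ground truth for parameter-recovery and
    calibration testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    mclust,
    withr,
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
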