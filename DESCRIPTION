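Package: poperosion
Title: Post-Bottleneck Genomic Erosion Analysis from SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-VCF population-genomic erosion analysis for small,
    bottlenecked populations: site filtering and LD pruning of biallelic SNP
    genotypes, KING-robust pairwise relatedness screening, observed
    heterozygosity and windowed nucleotide diversity, window-based runs of
    homozygosity (ROH) with the FROH inbreeding coefficient, ROH size classes
    and coalescence-time dating, closed-form linkage-disequilibrium estimators
    of contemporary and recent-history effective population size, and
    outgroup-polarized masked/realized/total genetic-load accounting.  Includes
    a forward-in-time Wright-Fisher simulator (recombination, deleterious
    mutation classes with dominance, diverged outgroups, pedigree pairs) that
    generates synthetic datasets with known truth for end-to-end validation,
    plus a stage-ordered pipeline driver with a run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
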