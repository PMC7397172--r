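Package: vinekin
Title: Microsatellite and SNP Fingerprinting, Diversity, Structure, and
    Parentage Analysis for Clonal Crop Germplasm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing germplasm collections of clonally
    propagated crops (grapevine in particular) with co-dominant markers:
    reading and harmonizing diploid SSR and biallelic SNP genotype tables,
    duplicate and synonym detection with an allele-mismatch tolerance,
    per-locus diversity and identity statistics (expected and observed
    heterozygosity, polymorphic information content, probability of
    identity for unrelated individuals and for full sibs, null-allele
    frequency, rarefied allelic richness, Hardy-Weinberg exact tests),
    marker-panel comparison, proportion-of-shared-alleles distances with
    UPGMA clustering and Newick export, Bayesian admixture inference by
    Gibbs sampling with Evanno model choice, replicate alignment and
    Q-threshold assignment, AMOVA with permutation tests, likelihood-based
    parentage assignment calibrated by offspring simulation with
    chloroplast-haplotype maternity designation, and a fully seeded
    synthetic-data generator providing ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
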