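Package: breedscan
Title: Bayesian Mixture-Model GWAS and Cross-Population EHH Selection
    Scans for Within-Breed Case/Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genetic mapping toolkit for within-breed case/control cohorts
    such as pedigree dog breeds. Implements a four-component normal-mixture
    ("BayesR"-type) Gibbs sampler that models all variant effects jointly,
    calls associated loci from posterior mean effect sizes, and summarises
    them as per-individual risk indices with ANOVA-based variance-explained
    decompositions. A companion selection-scan engine computes extended
    haplotype homozygosity (EHH), integrated EHH (iHH) and the
    cross-population XP-EHH statistic between case and control haplotype
    panels, with sliding-window candidate-region calling. Includes PLINK
    text/binary genotype I/O with standard QC filters, single-variant
    association tests, LD and haplotype-carrier utilities, and a
    haplotype-copying cohort simulator with liability-threshold phenotypes
    and injectable selective sweeps for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
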