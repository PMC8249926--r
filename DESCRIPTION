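Package: wchc
Title: Weighted Combination of Multiple Phenotypes Following Hierarchical
    Clustering for Genetic Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Association testing between a single genetic variant and
    multiple correlated quantitative phenotypes. Phenotypes are grouped by
    bottom-up hierarchical clustering with size-dependent correlation
    similarity (Pearson, multiple, and canonical correlation), each cluster
    is collapsed into an optimally weighted phenotype combination scored
    against an allele-level genotype expansion, and the per-cluster
    permutation p-values are combined by their minimum (WCHC).  Includes
    the un-clustered weighted-combination test (WCmulP), classical
    comparators (O'Brien, SHet, TATES, MANOVA, proportional-odds reverse
    regression), a factor-model phenotype simulator, and drivers for
    type-I-error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
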