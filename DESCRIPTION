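Package: cpgclust
Title: Consensus Clustering and Differential Analysis of CpG Promoter
    Methylation Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quality control and beta-value filtering for two-channel CpG
    methylation bead arrays, subsampled k-means consensus clustering of the
    most variant probes with consensus-based selection of the cluster number,
    covariate-adjusted differential methylation on logit-transformed beta
    values with Benjamini-Hochberg false discovery rate control, Kaplan-Meier
    and Cox proportional-hazards survival comparison of methylation clusters,
    and hypergeometric gene-set over-representation analysis against the
    array's gene background. Includes a synthetic-data generator emulating a
    population-based breast-tumor methylation cohort (latent clusters with a
    globally hypermethylated subclass, cluster-linked clinical covariates,
    replicate samples, controlled QC failures, cluster-dependent survival, and
    methylation-anticorrelated expression) so that the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
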