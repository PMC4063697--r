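Package: bonesite
Title: Skeletal-Site Dissection of Bone Mineral Density by GWAS,
    Meta-Analysis and Variance Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end toolkit for dissecting the genetics of bone mineral
    density (BMD) across skeletal sites from total-body DXA scans. Provides a
    synthetic two-cohort genotype-dosage and multi-trait phenotype generator
    with genotype quality control (minor allele frequency, call rate,
    Hardy-Weinberg exact test); per-cohort single-SNP association on
    covariate-residualized standardized traits with ancestry principal
    components and genomic control; allele-harmonized inverse-variance
    fixed-effects meta-analysis with Cochran's Q and I-squared; a
    trivariate-normal likelihood-ratio test of skeletal-site-specific SNP
    effects combined across cohorts by Fisher's product; individual-level
    conditional association with Nyholt effective-test locus thresholds; and
    genetic-relationship-matrix based univariate and bivariate REML estimation
    of SNP-heritability and genetic/residual correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
RoxygenNote: 7.3.3
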