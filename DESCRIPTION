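Package: clonescan
Title: Multivariate Mixed-Model GWAS for Clonally Replicated Field Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide association analysis of longitudinal quantitative
    traits measured on clonally replicated full-sib progeny in randomized
    complete block designs. Implements genotype quality control for outbred
    F1 segregation types (1:1, 1:2:1, 1:1:1:1), restricted maximum likelihood
    estimation of multivariate genetic and residual covariance components
    under a Kronecker-structured covariance with a pedigree relationship
    matrix, vectorized Wald F tests of per-marker genotype effects,
    Bonferroni thresholding with sub-kilobase region collapsing, a two-stage
    univariate comparison scan, descriptive and post-hoc summaries, and a
    synthetic-data generator emulating the target population and design.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
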