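Package: gestmr
Title: Metabolite GWAS and One-Sample Mendelian Randomization for
    Gestational Dysglycemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An ethnic-stratified pipeline linking maternal metabolite
    levels to gestational dysglycemia by one-sample Mendelian
    randomization. Provides a synthetic two-stratum pregnancy cohort
    simulator with known ground truth (relatedness, polygenic metabolite
    architecture, confounding, pleiotropy), metabolite preparation
    (IQR outlier removal, log/sqrt/normal-score transforms, glucose
    log-normalisation and GDM flagging), mixed-linear-model association
    scans with leave-one-chromosome-out genetic relationship matrices
    and genomic-inflation diagnostics, fixed-effect inverse-variance
    meta-analysis with I-squared heterogeneity, LD-thinned
    genetic-risk-score instruments, two-stage least squares with
    Wu-Hausman, leave-one-out and SNP-exclusion sensitivity analyses,
    composite metabolite-class exposures via PCA, and analytic and
    Monte-Carlo MR power calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
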