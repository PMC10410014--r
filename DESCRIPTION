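Package: frailtymr
Title: Metabolic Biomarker Screening, Meta-Analysis, and Mendelian
    Randomization for Frailty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying metabolic biomarkers of frailty:
    construction of the deficit-accumulation frailty index (including
    category-stripped variants) and the frailty phenotype score,
    covariate-adjusted association screening with Bonferroni control and
    cluster-robust standard errors, LASSO feature selection with the
    one-standard-error rule, DerSimonian-Laird random-effects replication
    meta-analysis, a complete two-sample Mendelian randomization engine
    (instrument clumping, allele harmonization, IVW, MR-Egger, weighted
    median, weighted mode, MR-PRESSO, Cochran's Q, FDR control,
    pleiotropy-pruned instruments), and co-twin control analysis.  A
    synthetic-data module generates cohorts, twin samples, and paired GWAS
    summary statistics with known truth so every stage is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    glmnet,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
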