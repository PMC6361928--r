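Package: gweis
Title: Genome-Wide by Environment Interaction Analysis and GxE-Weighted
    Polygenic Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide by environment interaction studies
    (GWEIS) of quantitative traits with count-valued environmental
    exposures such as stressful life events. Implements per-SNP additive
    association scans and interaction scans with heteroscedasticity-robust
    (Huber-White) covariance, a 1-df Wald test of the SNP-by-environment
    term and a 2-df joint Wald test of the SNP main and interaction
    effects, genomic-control inflation diagnostics, polygenic risk scores
    weighted by additive, interaction or combined joint effects via
    greedy LD clumping and p-value thresholding, and incremental
    prediction evaluation through nested regression models,
    likelihood-ratio tests, permutation empirical p-values and false
    discovery rate adjustment. Ships a synthetic-data generator with
    controllable additive, interaction and gene-environment-correlation
    architecture plus PLINK 1.x binary genotype input/output, so the full
    pipeline runs end-to-end without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
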