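Package: drvar
Title: Survival Analysis and Variance Decomposition for Dietary Restriction
    Lifespan Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for factorial Drosophila dietary-restriction
    (DR) lifespan experiments run across laboratories. Provides from-scratch
    survival estimators (Kaplan-Meier product-limit curves and medians,
    two-group log-rank tests, Cox proportional-hazards fitting by
    Newton-Raphson on the partial likelihood with Efron or Breslow tie
    corrections, Cox-Snell pseudo R-squared, and a Schoenfeld-residual check
    of the proportional-hazards assumption), a likelihood-based decomposition
    of lifespan variance into per-factor contributions (lab, cohort,
    genotype, sex, diet), a Bonferroni-corrected battery of per-stratum DR
    versus AL log-rank comparisons with direction calls, cross-laboratory
    concordance summaries via Spearman rank correlation, and a Gompertz
    lifespan simulator with the study's 2 lab x 4 cohort x 4 genotype x
    2 sex x 2 diet factorial design and right censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
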