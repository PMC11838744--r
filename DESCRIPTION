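Package: gers
Title: Gene Expression Risk Scores for Onset-Class Association in Family Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds transcriptome-imputed gene expression risk scores (GeRS)
    and p-value-thresholded polygenic risk scores from genotype dosages,
    SNP-expression weight models and GWAS summary statistics; aggregates
    gene-level scores over coexpression modules and network hub genes; and
    tests their association with early- versus late-onset disease status
    using family-aware mixed-effects logistic regression, Nagelkerke
    pseudo-R-squared model comparison and random-effects meta-analysis.
    Includes a synthetic-cohort generator (sibship and simplex designs with
    planted gene effects, hub networks and summary statistics) so the whole
    pipeline is testable end to end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    metafor,
    igraph,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
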