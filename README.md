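# gers

Gene expression risk scores (GeRS) for testing whether genetically
regulated gene expression separates **early-onset** from **late-onset**
disease, in family-based (sibship) and unrelated case cohorts. The package
is aimed at psychiatric-genetics analysts who have post-imputation genotype
dosages, a cis SNP-expression weight model (PredictDB-style), GWAS summary
statistics, coexpression-module gene lists and a gene-interaction edge
list — and who want the whole chain from dosages to a pooled adjusted odds
ratio to be reproducible and testable.

## What it computes

For individual *i* and gene *g* with cis weights *w<sub>lg</sub>* and
ALT dosages *X<sub>il</sub>*:

- **predicted expression** (transcriptome imputation):
  *Ê<sub>ig</sub> = Σ<sub>l</sub> w<sub>lg</sub> X<sub>il</sub>*, after
  allele harmonization;
- **TWAS effect sizes** from summary statistics, weights and an LD
  reference panel:
  *z<sub>g</sub> = Σ<sub>l</sub> w<sub>lg</sub> (σ<sub>l</sub>/σ<sub>g</sub>) z<sub>l</sub>*
  with *σ<sub>g</sub>² = wᵀΣw*;
- **gene GeRS** *s<sub>ig</sub> = z<sub>g</sub> Ê<sub>ig</sub>*, summed
  over module gene lists (module GeRS) or over network **hub genes**
  (genes regulating ≥ 4 others in the top-ranking interaction network);
- **PRS** by p-value thresholding, six thresholds by default with a
  0.05/6 Bonferroni cutoff;
- **association**: each z-standardized score against onset class via
  family random-intercept logistic regression (sibship cohorts) or plain
  logistic regression (unrelated cohorts), adjusted for sex, education and
  four ancestry PCs, with the change in Nagelkerke pseudo-R² between the
  covariates-only and full models;
- **meta-analysis**: cohort log-ORs pooled by inverse-variance REML
  random effects.

Because the real inputs of such studies are not redistributable, a
first-class synthetic-data module generates sibship and simplex cohorts,
weight models, summary statistics, phenotypes and hub networks with known
ground truth, so every stage is validated end to end (parameter recovery,
null calibration, and independent numerical oracles).

## Worked example

A complete run on a synthetic sibship cohort with a module effect of
aOR 1.38 per SD planted on the module score:

```r
library(gers)

cfg <- sim_config(n_families = 300, sibs_per_family = 2, n_variants = 60,
                  n_genes = 20, snps_per_gene = 3,
                  gwas_gene_effects = setNames(rep(c(0.15, -0.15), 10),
                                               sprintf("g%03d", 1:20)),
                  seed = 42)
cohort    <- generate_genotypes(cfg)
weights   <- generate_weight_model(cfg)
sumstats  <- generate_summary_stats(cfg, weights)
twas      <- summary_twas(weights, sumstats, ld_ref = cohort$genotypes)
harmon    <- harmonize_weights(weights, cohort$genotypes)
expr      <- predict_expression(cohort$genotypes, harmon)
gene_sc   <- gene_gers(expr, twas)
module_sc <- module_gers(gene_sc, module_definition("M10", cfg$genes))
pheno <- generate_phenotypes(cohort$genotypes, weights, cfg, cohort$pedigree,
                             planted_score = module_sc$raw,
                             planted_log_or = log(1.38))
d <- merge(pheno, scores_wide(module_sc), by = "individual")
fit_mixed_logistic(d, "module:M10", c("sex", "education", paste0("PC", 1:4)))
#> module:M10 [mixed logistic]: aOR = 1.534 (95% CI 1.265-1.861), p = 1.4e-05,
#>   delta pseudo-R2 = 0.0390, n = 600
```

The adjusted odds ratio of 1.53 per SD of the module score is this
cohort's noisy estimate of the planted 1.38; the pseudo-R² change says the
score explains about 3.9% of onset-class variance beyond the covariates.
Pooling a multiplex and a simplex cohort in one call:

```r
rep <- gers_pipeline_replicate(seed = 42, true_aor = 1.38)
rep$meta
#> meta-analysis (k = 2): pooled aOR = 1.405 (95% CI 1.193-1.654),
#>   p = 4.52e-05, tau2 = 0.004998
```

Over 200 such replicates (`gers_recovery_study()`) the pooled estimates
center on the planted value and the 95% CI covers it in about 95% of
replicates; that study is what the acceptance script below reruns.

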