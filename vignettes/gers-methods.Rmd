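---
title: "Methods: gene expression risk scores for onset-class association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene expression risk scores for onset-class association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

The package studies whether genetically regulated gene expression separates
early-onset (first psychotic episode at or before 18 years) from late-onset
cases. It chains four standard genetic-epidemiology components:

1. **Transcriptome imputation.** Given a cis SNP-expression weight model
   (gene $g$, variants $l$, weights $w_{lg}$ per effect-allele count), the
   predicted expression of individual $i$ is the linear predictor
   $\hat E_{ig} = \sum_l w_{lg} X_{il}$ over the ALT-allele dosages
   $X_{il} \in [0,2]$. Weights are harmonized to the genotype allele coding
   first: an effect allele equal to REF flips the weight's sign and adds a
   per-gene constant $2 w_{lg}$, which we track for raw-scale correctness
   even though every downstream score is z-standardized and constants
   cancel.

2. **TWAS effect sizes.** Gene-level disease association is computed from
   GWAS summary statistics, the same weights and an LD reference panel:
   $$z_g = \sum_l w_{lg} \frac{\sigma_l}{\sigma_g} z_l, \qquad
     \sigma_g^2 = w^\top \Sigma w,$$
   with $\sigma_l$ the dosage SD of variant $l$ in the panel and $\Sigma$
   the panel dosage covariance. An individual-level TWAS (per-gene logistic
   regression on predicted expression) serves as its validation oracle: in
   the regime where the LD reference *is* the GWAS cohort the two agree to
   numerical tolerance, and the test suite checks correlation above 0.95 on
   a 50,000-individual synthetic cohort.

3. **Risk scores.** The gene expression risk score (GeRS) multiplies
   predicted expression by the gene's TWAS effect size,
   $s_{ig} = z_g \hat E_{ig}$; module scores sum $s_{ig}$ over a
   coexpression-module gene list, hub scores over the module's hub genes.
   The polygenic risk score at threshold $t$ sums
   $\beta_l X_{il}$ over variants with GWAS $p_l < t$. All scores are
   z-standardized within the analyzed cohort (sample-SD, $n-1$,
   convention), so reported odds ratios are per SD.

4. **Association and pooling.** Early- vs late-onset status is regressed on
   each z-scored risk score with sex, education and four ancestry PCs as
   covariates: a family random-intercept logistic model for sibship
   (multiplex) cohorts, plain logistic regression for simplex cohorts.
   Explained variance is the change in Nagelkerke pseudo-$R^2$,
   $$R^2_N = \frac{1 - (L_0/L_1)^{2/n}}{1 - L_0^{2/n}},$$
   between the covariates-only and covariates-plus-score models ($L_0$ the
   intercept-only likelihood). Cohort estimates are pooled by
   inverse-variance random-effects meta-analysis with $\tau^2$ estimated by
   REML.

## Hub genes

Hub detection re-implements, as an open rule, the proprietary
network-analysis step often run in commercial pathway tools: induce the
subgraph of a gene-interaction database on the focus genes and their direct
interactors, split into weakly connected components, score each component
by $-\log_{10}$ of the hypergeometric right-tail probability of its
focus-gene content (the published description of that score family; an
approximation, clearly not the proprietary score itself), and call a focus
gene a hub when it regulates **four or more** distinct other genes
(out-edges; the boundary is inclusive) in the top-ranking network. Whether
indirect ("broken-line") relations count toward the degree is not
standardized, so both relation tags count by default and undirected edges
can be included with `count_undirected = TRUE`.

## The synthetic-data generator

Real cohorts of this design (family-based schizophrenia samples, brain
SNP-expression weights, consortium GWAS summary statistics) cannot be
redistributed, so the generator emulates each input with known ground
truth:

* **Genotypes.** Each gene owns a disjoint block of `snps_per_gene` cis
  variants with ALT frequencies drawn from `maf_range` (default
  0.05–0.5). Siblings are produced by Mendelian transmission from two
  unobserved parents, giving the kinship-expected sib-pair dosage
  correlation of 0.5; `sibs_per_family = 1` yields unrelated founders.
  Variants are in linkage equilibrium by default; `ld_rho` switches on an
  AR(1) latent-Gaussian haplotype process that produces decaying LD for
  the summary-TWAS reference panel. INFO is constant 1 (simulated
  genotypes are observed); imputation-quality variation is out of scope.
* **Weights.** Sparse cis weights drawn from $N(0, 0.2^2)$; the scale is
  arbitrary because downstream scores are standardized.
* **Summary statistics.** A GWAS trait is modelled as a linear combination
  of standardized true gene expressions with coefficients
  `gwas_gene_effects`; under linkage equilibrium the induced marginal beta
  of variant $l$ in gene $g$ is exactly $\gamma_g w_{lg}/\mathrm{sd}(E_g)$,
  to which noise with $SE = 1/\sqrt{2f(1-f)N}$ is added. The default
  $N = 320{,}403$ matches a large psychiatric case-control GWAS
  (76,755 cases, 243,648 controls). A mega-cohort regression oracle in the
  test suite confirms the induced values.
* **Phenotypes.** Early-onset labels follow
  $\mathrm{logit}\,P(\text{early}) = \alpha + \sum_g \beta_g z(E_g) +
  \text{covariates} + u_f$, $u_f \sim N(0, \tau^2)$, with $\alpha$ solved
  so the expected early-onset fraction matches a target (default
  $223/595$, mirroring the published multiplex group sizes; the matched
  subsample fraction differs between cohorts in practice, so the fraction
  is a parameter, not a constant). Sex and education covariate effects
  default to $(0, -0.2)$ per year — early onset associated with less
  completed education, plausible for an illness interrupting schooling —
  and are generated independently of genotype; $\tau^2$ defaults to 0.5, a
  moderate familial clustering.
* **Networks.** `generate_network()` plants exactly `n_hubs` genes with
  out-degree at least `min_out_degree` (default 4) and keeps every other
  gene strictly below the threshold, so hub recovery has an exact answer.

What the generator does **not** emulate: realistic LD from reference
panels, haplotype phasing, allele-frequency spectra, cross-gene eQTL
sharing (cis sets are disjoint by design so the mega-cohort oracle is
exact), genotyping batch structure, or ascertainment. Passing tests
therefore demonstrate correctness of the algorithms and calibration of the
inference under the stated model, not robustness to every artefact of real
genotype data.

## Parameter-recovery design

The recovery harness (`gers_pipeline_replicate()`) plants the onset effect
directly on the standardized module (or hub) GeRS *as the pipeline computes
it* — true weights, TWAS effect sizes derived from the generated summary
statistics at the configured GWAS sample size. The coefficient of the
analyzed score is then the exact estimand of the association stage, so CI
coverage isolates the correctness of the mixed/plain logistic fits and the
REML pooling rather than mixing in attenuation from score-estimation noise
(which is what the separate TWAS-concordance and summary-statistics oracle
checks quantify). Per-gene planting (`true_gene_effects`) remains available
and drives the null-calibration and TWAS-concordance studies.

Replicated studies use scaled-down sizes chosen to keep Monte-Carlo error
small while the whole suite stays convenient to run: 300 sibship families
(600 affected sibs) plus 595 unrelated cases per replicate, 20 genes with
3 cis variants each, 200 replicates for coverage of the planted
aOR = 1.38 (and 100 for the hub-level aOR = 1.22), and 500 replicates for
null calibration of the multiplex mixed model.

## Numerical and design choices

* **QC thresholds.** Removal rules are INFO < 0.8 and MAF below the
  cutoff, with boundaries kept. The default `maf_min = 0.01` is the
  conventional post-imputation choice; the aggressive 0.1 reported in some
  family-based analyses is one flag away (`maf_min = 0.1`). A variant
  failing both filters is counted once, under INFO. QC is idempotent.
* **Which TWAS statistic weights the GeRS.** The native summary-TWAS
  statistic is the z-score, and it is the default `effect`; a beta-like
  $z_g/\sigma_g$ is available via `effect = "z_over_sigma"`. Because
  scores are standardized afterwards, the choice rescales gene
  contributions but both are supported and tested.
* **Strand-ambiguous variants** (A/T, C/G) are dropped during
  harmonization by default — without frequency-based inference their
  orientation is undecidable; a flag retains them for same-strand data.
* **Missing dosages** contribute nothing to a prediction (term omission,
  the common transcriptome-imputation practice); mean substitution is
  available via `missing_action = "mean"`. For PCA, missing dosages are
  mean-imputed per variant.
* **PCA** uses the SVD of column-standardized dosages with a
  deterministic sign convention (largest-magnitude loading positive). No
  LD pruning is applied by default; the synthetic data are already in
  near-linkage equilibrium.
* **PRS grid.** Six thresholds {5e-8, 1e-4, 1e-3, 0.01, 0.05, 0.1},
  consistent with a 0.05/6 Bonferroni cutoff and spanning the
  conventionally reported best-performing values (0.1, 0.01). Clumping is
  off by default (linkage-equilibrium data); when enabled, greedy
  lowest-p-first selection with $r^2 > 0.1$ within 500 kb.
* **Summary-TWAS stability.** The reference covariance gets a ridge of
  1e-8 on the diagonal; genes whose predicted variance is indistinguishable
  from that floor are excluded with a reason rather than scored.
* **Mixed-model pseudo-$R^2$.** How Nagelkerke's formula extends to a
  GLMM is genuinely open; we plug the integrated (marginal) likelihoods of
  the fitted random-intercept models into the same formula (the
  intercept-only model also carries the random intercept), with a
  conditional-likelihood variant behind `r2_likelihood = "conditional"`.
* **Mixed-model fitting** uses Laplace (`nAGQ = 1`) by default with
  adaptive Gauss–Hermite available through `nAGQ`; a hand-written
  quadrature likelihood maximized by general-purpose optimization is the
  test oracle. Wald (not profile) CIs are reported throughout, matching
  the standard reporting of adjusted odds ratios.
* **Meta-analysis** is random-effects REML by default (fixed-effect mode
  exists for the $\tau^2 = 0$ check), with $\tau^2$ floored at zero; a
  grid-plus-golden-section maximizer of the restricted likelihood is the
  independent oracle.
* **Ties and degenerate inputs.** Best-threshold ties go to the smaller
  threshold; zero-variance scores are flagged and emitted as z = 0; a
  threshold passed by no variant yields a flagged zero score; empty module
  intersections and empty hub lists are errors naming the offending set;
  separation in a logistic fit is flagged rather than reported as a finite
  estimate.

## Known limitations

* The hub rule reproduces a published *selection rule*, not the numeric
  scores of any proprietary network tool; score thresholds on our
  enrichment scale are configurable but not comparable across tools.
* The generator's disjoint-cis assumption removes cross-gene LD
  confounding; real weight databases share variants across genes.
* Family-based ascertainment (affected sib pairs) is emulated only through
  the random intercept; no liability-threshold selection of families is
  modelled.
* Education is the only non-genetic risk covariate with a non-zero default
  effect; genotype-covariate confounding is off by default and enabled
  explicitly through `sim_config(confounding = ...)`, which ties education
  to the individual's genetic score for robustness studies.
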