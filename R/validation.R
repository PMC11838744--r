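#' Run the full pipeline once on a planted two-cohort design
#'
#' One replicate of the end-to-end validation design: a sibship (multiplex)
#' cohort and an unrelated (simplex) cohort share one genetic architecture
#' (variants, cis weights, GWAS summary statistics with gene effects planted
#' on the module genes). Gene-level TWAS effect sizes are derived by the
#' summary TWAS against the multiplex panel as LD reference; expression is
#' predicted per cohort; gene scores are aggregated over the module (or its
#' hub subset). The onset phenotype is then drawn with the planted log-odds
#' `log(true_aor)` per SD of that aggregated score, so the coefficient of
#' the analyzed score is the exact estimand of the association stage. Each
#' cohort is fitted with its standard model (random-intercept logistic for
#' the multiplex cohort, plain logistic for the simplex cohort, both with
#' sex, education and four PC covariates) and the two estimates are pooled
#' by REML random-effects meta-analysis.
#'
#' @param seed integer seed for this replicate.
#' @param true_aor planted adjusted odds ratio per SD of the aggregated
#'   score (1 gives the global null).
#' @param level `"module"` (sum over all module genes) or `"hub"` (sum over
#'   `n_hub_genes` of them).
#' @param n_families multiplex families (2 sibs each).
#' @param simplex_n simplex individuals.
#' @param n_genes,snps_per_gene,n_variants genetic architecture sizes.
#' @param n_hub_genes hub-subset size used when `level = "hub"`.
#' @param gwas_gamma magnitude of the per-gene effects planted in the GWAS
#'   summary statistics (alternating sign across genes).
#' @param tau2 family random-intercept variance of the onset model.
#' @param nAGQ quadrature order for the mixed fit.
#' @param pseudo_r2 compute the Nagelkerke pseudo-R-squared change (extra
#'   refits; replicate studies that only need the estimate turn it off).
#' @return list with `multiplex` and `simplex` `association_result`s, the
#'   pooled `meta` result and `true_log_or`.
#' @export
gers_pipeline_replicate <- function(seed, true_aor = 1.38,
                                    level = c("module", "hub"),
                                    n_families = 300L, simplex_n = 595L,
                                    n_genes = 20L, snps_per_gene = 3L,
                                    n_variants = 60L, n_hub_genes = 6L,
                                    gwas_gamma = 0.15, tau2 = 0.5,
                                    nAGQ = 1L, pseudo_r2 = TRUE) {
  level <- match.arg(level)
  genes <- sprintf("g%03d", seq_len(n_genes))
  gamma <- stats::setNames(gwas_gamma * rep_len(c(1, -1), n_genes), genes)
  cfg_m <- sim_config(n_families = n_families, sibs_per_family = 2L,
                      n_variants = n_variants, n_genes = n_genes,
                      snps_per_gene = snps_per_gene,
                      gwas_gene_effects = gamma, tau2 = tau2, seed = seed)
  cfg_s <- sim_config(n_families = simplex_n, sibs_per_family = 1L,
                      n_variants = n_variants, n_genes = n_genes,
                      snps_per_gene = snps_per_gene,
                      gwas_gene_effects = gamma, tau2 = 0, seed = seed,
                      geno_seed = seed + 500000L)

  wm <- generate_weight_model(cfg_m)
  ss <- generate_summary_stats(cfg_m, wm)
  gm <- generate_genotypes(cfg_m)
  gs <- generate_genotypes(cfg_s)
  tw <- summary_twas(wm, ss, ld_ref = gm$genotypes)

  score_genes <- if (level == "module") genes else
    genes[seq_len(min(n_hub_genes, n_genes))]
  module <- module_definition("M10", genes)

  one_cohort <- function(cohort, cfg, mixed) {
    hw <- harmonize_weights(wm, cohort$genotypes)
    expr <- predict_expression(cohort$genotypes, hw)
    gg <- gene_gers(expr, tw)
    agg <- if (level == "module") {
      module_gers(gg, module)
    } else {
      hub_gers(gg, score_genes, id = "M10")
    }
    ph <- generate_phenotypes(cohort$genotypes, wm, cfg, cohort$pedigree,
                              planted_score = agg$raw,
                              planted_log_or = log(true_aor))
    d <- merge(ph, scores_wide(agg), by = "individual")
    covs <- c("sex", "education", paste0("PC", 1:4))
    score_col <- unique(agg$score)
    if (mixed) {
      fit_mixed_logistic(d, score_col, covs, nAGQ = nAGQ, pseudo_r2 = pseudo_r2)
    } else {
      fit_logistic(d, score_col, covs)
    }
  }

  res_m <- one_cohort(gm, cfg_m, mixed = TRUE)
  res_s <- one_cohort(gs, cfg_s, mixed = FALSE)
  meta <- meta_analyze(list(res_m, res_s), labels = c("multiplex", "simplex"))
  list(multiplex = res_m, simplex = res_s, meta = meta,
       true_log_or = log(true_aor))
}

#' Parameter-recovery study for a planted module effect
#'
#' Repeats [gers_pipeline_replicate()] and records, per replicate, the
#' pooled estimate and whether the REML random-effects 95% CI covers the
#' planted odds ratio.
#'
#' @param n_reps number of replicates.
#' @param true_aor planted odds ratio per SD.
#' @param seed base seed; replicate r uses `seed + 7919 * r`.
#' @param ... passed to [gers_pipeline_replicate()].
#' @return data frame with one row per replicate (estimate, se, ci bounds,
#'   covered, p values per cohort) and a `coverage` attribute.
#' @export
gers_recovery_study <- function(n_reps = 200L, true_aor = 1.38, seed = 1L, ...) {
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    rep <- gers_pipeline_replicate(seed = seed + 7919L * r, true_aor = true_aor,
                                   pseudo_r2 = FALSE, ...)
    m <- rep$meta
    rows[[r]] <- data.frame(
      rep = r, aOR = m$aOR, se = m$se,
      ci_lower = m$ci_lower, ci_upper = m$ci_upper,
      covered = m$ci_lower <= true_aor & true_aor <= m$ci_upper,
      p_multiplex = rep$multiplex$p, p_simplex = rep$simplex$p,
      tau2 = m$tau2
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "coverage") <- mean(out$covered)
  out
}

#' Null-calibration study for the multiplex module-GeRS model
#'
#' Generates cohorts with no planted onset effect (labels independent of
#' genotype given covariates and the family intercept), runs the pipeline
#' and fits the multiplex module-GeRS mixed model, returning the
#' per-replicate association p-values. Under the null these are uniform and
#' the rejection rate at any alpha is nominal.
#'
#' @param n_reps number of replicates.
#' @param seed base seed.
#' @param n_families multiplex families (2 sibs each).
#' @param n_genes,snps_per_gene,n_variants architecture sizes.
#' @param gwas_gamma per-gene GWAS effect magnitude (keeps the TWAS
#'   weighting non-degenerate; onset stays null).
#' @param tau2 family random-intercept variance.
#' @param nAGQ quadrature order.
#' @return numeric vector of p-values with a `reject_rate_0.05` attribute.
#' @export
gers_null_calibration <- function(n_reps = 500L, seed = 1L, n_families = 300L,
                                  n_genes = 20L, snps_per_gene = 3L,
                                  n_variants = 60L, gwas_gamma = 0.15,
                                  tau2 = 0.5, nAGQ = 1L) {
  genes <- sprintf("g%03d", seq_len(n_genes))
  gamma <- stats::setNames(gwas_gamma * rep_len(c(1, -1), n_genes), genes)
  module <- module_definition("M10", genes)
  covs <- c("sex", "education", paste0("PC", 1:4))
  pvals <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    s <- seed + 7919L * r
    cfg <- sim_config(n_families = n_families, sibs_per_family = 2L,
                      n_variants = n_variants, n_genes = n_genes,
                      snps_per_gene = snps_per_gene,
                      gwas_gene_effects = gamma, tau2 = tau2, seed = s)
    wm <- generate_weight_model(cfg)
    ss <- generate_summary_stats(cfg, wm)
    gm <- generate_genotypes(cfg)
    tw <- summary_twas(wm, ss, ld_ref = gm$genotypes)
    hw <- harmonize_weights(wm, gm$genotypes)
    expr <- predict_expression(gm$genotypes, hw)
    gg <- gene_gers(expr, tw)
    msc <- module_gers(gg, module)
    ph <- generate_phenotypes(gm$genotypes, wm, cfg, gm$pedigree)
    d <- merge(ph, scores_wide(msc), by = "individual")
    pvals[r] <- fit_mixed_logistic(d, unique(msc$score), covs, nAGQ = nAGQ,
                                   pseudo_r2 = FALSE)$p
  }
  attr(pvals, "reject_rate_0.05") <- mean(pvals < 0.05)
  pvals
}

#' Concordance of summary-level and individual-level TWAS
#'
#' Generates one large cohort with LD blocks and planted gene effects on a
#' binary trait, derives empirical GWAS summary statistics from it
#' ([gwas_scan()]), then computes gene z-scores both ways: the summary TWAS
#' against the cohort itself as LD reference, and the individual-level TWAS
#' (per-gene logistic regression on predicted expression). Reports the
#' correlation and max |difference| across genes.
#'
#' @param n cohort size.
#' @param n_genes,snps_per_gene genetic architecture.
#' @param ld_rho AR(1) haplotype correlation (LD between cis variants).
#' @param effect_sd SD of the planted per-gene onset effects.
#' @param seed integer seed.
#' @return list with the two `twas_result`s, `correlation` and
#'   `max_abs_diff` over unflagged genes.
#' @export
twas_concordance <- function(n = 50000L, n_genes = 25L, snps_per_gene = 4L,
                             ld_rho = 0.35, effect_sd = 0.06, seed = 1L) {
  genes <- sprintf("g%03d", seq_len(n_genes))
  set.seed(seed)
  beta <- stats::setNames(stats::rnorm(n_genes, 0, effect_sd), genes)
  cfg <- sim_config(n_families = n, sibs_per_family = 1L,
                    n_variants = n_genes * snps_per_gene, n_genes = n_genes,
                    snps_per_gene = snps_per_gene,
                    true_gene_effects = beta, tau2 = 0,
                    ld_rho = ld_rho, early_fraction = 0.5, seed = seed)
  gm <- generate_genotypes(cfg)
  wm <- generate_weight_model(cfg)
  ph <- generate_phenotypes(gm$genotypes, wm, cfg, gm$pedigree)
  ss <- gwas_scan(gm$genotypes, ph$onset)
  tw_sum <- summary_twas(wm, ss, ld_ref = gm$genotypes)
  hw <- harmonize_weights(wm, gm$genotypes)
  expr <- predict_expression(gm$genotypes, hw)
  tw_ind <- individual_twas(expr, ph$onset)
  common <- intersect(tw_sum$gene, tw_ind$gene[!tw_ind$flagged])
  zs <- tw_sum$z[match(common, tw_sum$gene)]
  zi <- tw_ind$z[match(common, tw_ind$gene)]
  list(summary = tw_sum, individual = tw_ind,
       correlation = stats::cor(zs, zi),
       max_abs_diff = max(abs(zs - zi)))
}
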