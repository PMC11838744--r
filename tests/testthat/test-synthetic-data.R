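test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_families = 0), "positive")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(gwas_n = 0), "gwas_n")
  expect_error(generate_weight_model(
    sim_config(n_variants = 10, n_genes = 4, snps_per_gene = 3)
  ), "overlapping cis")
})

test_that("generation is fully deterministic under a fixed seed", {
  cfg <- sim_config(n_families = 40, n_variants = 30, n_genes = 6,
                    snps_per_gene = 3, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$weights$weight, b$weights$weight)
  expect_identical(a$sumstats$beta, b$sumstats$beta)
  expect_identical(a$phenotypes, b$phenotypes)
})

test_that("simplex cohorts are unrelated founders", {
  cfg <- sim_config(n_families = 100, sibs_per_family = 1, n_variants = 20,
                    n_genes = 4, snps_per_gene = 3, seed = 3)
  gp <- generate_genotypes(cfg)
  expect_true(all(gp$pedigree$founder))
  expect_equal(length(unique(gp$pedigree$family)), 100)
})

test_that("dosages behave like binomial allele counts", {
  cfg <- sim_config(n_families = 4000, sibs_per_family = 1, n_variants = 3,
                    n_genes = 1, snps_per_gene = 1,
                    maf_range = c(0.5, 0.5), seed = 5)
  gp <- generate_genotypes(cfg)
  expect_true(all(gp$genotypes$dosages %in% 0:2))
  # MAF fixed at 0.5 -> mean dosage about 1 per variant
  expect_equal(unname(colMeans(gp$genotypes$dosages)), rep(1, 3),
               tolerance = 0.05)
})

test_that("sib pairs show the kinship-expected dosage correlation of 0.5", {
  cfg <- sim_config(n_families = 2000, sibs_per_family = 2, n_variants = 1,
                    n_genes = 1, snps_per_gene = 1,
                    maf_range = c(0.3, 0.3), seed = 11)
  gp <- generate_genotypes(cfg)
  d <- gp$genotypes$dosages[, 1]
  fam <- gp$pedigree$family
  sib1 <- d[match(unique(fam), fam)]
  sib2 <- d[length(d) + 1 - match(unique(fam), rev(fam))]
  # closed-form expectation: 2 * kinship(sib, sib) = 0.5
  expect_equal(cor(sib1, sib2), 0.5, tolerance = 0.06)
  # and unrelated individuals (across families) are uncorrelated
  expect_lt(abs(cor(sib1, sib2[sample(length(sib2))])), 0.1)
})

test_that("weight model covers degenerate settings", {
  cfg0 <- sim_config(n_variants = 10, n_genes = 3, snps_per_gene = 0, seed = 2)
  wm0 <- generate_weight_model(cfg0)
  expect_equal(nrow(wm0), 0)
  expect_equal(attr(wm0, "genes"), cfg0$genes)

  cfg <- sim_config(n_variants = 12, n_genes = 3, snps_per_gene = 2,
                    weight_sd = 0, seed = 2)
  wm <- generate_weight_model(cfg)
  expect_true(all(wm$weight == 0))
  gp <- generate_genotypes(cfg)
  hw <- harmonize_weights(wm, gp$genotypes)
  expr <- predict_expression(gp$genotypes, hw)
  expect_true(all(expr == 0))
})

test_that("null summary statistics are calibrated", {
  cfg <- sim_config(n_variants = 4000, n_genes = 10, snps_per_gene = 2,
                    seed = 9)
  wm <- generate_weight_model(cfg)
  ss <- generate_summary_stats(cfg, wm)
  # all gene effects zero: z standard-normal, lambda about 1
  expect_equal(mean(ss$z), 0, tolerance = 0.05)
  expect_equal(sd(ss$z), 1, tolerance = 0.05)
  expect_equal(genomic_inflation(p = ss$p), 1, tolerance = 0.07)
  expect_equal(ss$z, ss$beta / ss$se)
  expect_equal(ss$p, 2 * pnorm(-abs(ss$z)))
})

test_that("summary statistics shrink to the truth as gwas_n grows", {
  genes <- sprintf("g%03d", 1:2)
  eff <- setNames(c(0.5, 0), genes)
  cfg <- sim_config(n_variants = 6, n_genes = 2, snps_per_gene = 3,
                    gwas_gene_effects = eff, gwas_n = 1e9, seed = 13)
  wm <- generate_weight_model(cfg)
  ss <- generate_summary_stats(cfg, wm)
  hit <- ss$variant %in% wm$variant[wm$gene == "g001"]
  expect_true(all(ss$p[hit & abs(ss$beta) > 1e-4] < 1e-20))
  expect_true(all(abs(ss$beta[!hit]) < 1e-3))
})

test_that("induced marginal betas match a mega-cohort regression oracle", {
  genes <- sprintf("g%03d", 1:3)
  eff <- setNames(c(0.4, -0.3, 0), genes)
  cfg <- sim_config(n_families = 60000, sibs_per_family = 1, n_variants = 9,
                    n_genes = 3, snps_per_gene = 3, gwas_gene_effects = eff,
                    gwas_n = 1e5, seed = 17)
  wm <- generate_weight_model(cfg)

  # average observed beta over replicate draws of the summary statistics
  # (same genetic architecture, fresh draw-level noise via geno_seed)
  reps <- lapply(1:100, function(r) {
    cfg_r <- cfg
    cfg_r$geno_seed <- cfg$seed + 1000L + r
    generate_summary_stats(cfg_r, wm)$beta
  })
  mean_beta <- rowMeans(do.call(cbind, reps))

  # oracle: regress the generating trait on each variant in a mega-cohort
  gp <- generate_genotypes(cfg)
  X <- gp$genotypes$dosages
  y <- numeric(nrow(X))
  for (g in genes) {
    wg <- wm[wm$gene == g, ]
    e <- drop(X[, wg$variant] %*% wg$weight)
    if (sd(e) > 0) y <- y + eff[[g]] * (e - mean(e)) / sd(e)
  }
  oracle <- apply(X, 2, function(x) coef(lm(y ~ x))[2])
  expect_equal(unname(mean_beta), unname(oracle), tolerance = 0.02)
})

test_that("phenotype generator hits the target early-onset fraction", {
  cfg <- sim_config(n_families = 3000, sibs_per_family = 1, n_variants = 8,
                    n_genes = 2, snps_per_gene = 2,
                    early_fraction = 223 / 595, tau2 = 0, seed = 19)
  co <- simulate_cohort(cfg)
  expect_equal(mean(co$phenotypes$onset), 223 / 595, tolerance = 0.03)
  expect_true(all(c("sex", "education", "PC1", "PC4") %in% names(co$phenotypes)))
})

test_that("with tau2 = 0 mixed and plain logistic fits agree", {
  cfg <- sim_config(n_families = 250, sibs_per_family = 2, n_variants = 8,
                    n_genes = 2, snps_per_gene = 2, tau2 = 0, seed = 23)
  gp <- generate_genotypes(cfg)
  wm <- generate_weight_model(cfg)
  sc <- rowSums(gp$genotypes$dosages)
  d <- generate_phenotypes(gp$genotypes, wm, cfg, gp$pedigree,
                           planted_score = sc, planted_log_or = 0.3)
  d$score <- as.numeric(scale(sc))
  fm <- fit_mixed_logistic(d, "score", c("sex", "education"))
  fp <- fit_logistic(d, "score", c("sex", "education"))
  expect_equal(fm$estimate, fp$estimate, tolerance = 0.05)
  expect_lt(fm$tau2, 0.1)
})

test_that("planted network hubs are exactly recoverable", {
  genes <- sprintf("G%02d", 1:30)
  # no hubs planted -> hub detection returns empty
  net0 <- generate_network(genes, n_hubs = 0, seed = 4)
  expect_length(identify_hubs(net0), 0)

  net <- generate_network(genes, n_hubs = 6, min_out_degree = 4, seed = 4)
  hubs <- identify_hubs(net, min_regulated = 4)
  expect_setequal(hubs, attr(net, "planted_hubs"))
  expect_length(hubs, 6)

  expect_error(generate_network(genes[1:3], n_hubs = 2, min_out_degree = 4),
               "infeasible")
  expect_error(generate_network(genes, n_hubs = 40), "exceeds")
})

test_that("a gene regulating exactly the threshold count is a hub", {
  edges <- data.frame(from = rep("A", 4), to = paste0("T", 1:4))
  net <- network_graph(edges, focus = c("A", paste0("T", 1:4)))
  expect_equal(identify_hubs(net, min_regulated = 4), "A",
               ignore_attr = TRUE)
  net3 <- network_graph(edges[1:3, ], focus = c("A", paste0("T", 1:3)))
  expect_length(identify_hubs(net3, min_regulated = 4), 0)
})

test_that("the confounding switch ties education to genetic risk", {
  genes <- sprintf("g%03d", 1:4)
  base <- sim_config(n_families = 2000, sibs_per_family = 1, n_variants = 8,
                     n_genes = 4, snps_per_gene = 2,
                     true_gene_effects = setNames(rep(0.5, 4), genes),
                     tau2 = 0, seed = 29)
  conf <- sim_config(n_families = 2000, sibs_per_family = 1, n_variants = 8,
                     n_genes = 4, snps_per_gene = 2,
                     true_gene_effects = setNames(rep(0.5, 4), genes),
                     confounding = 1.5, tau2 = 0, seed = 29)
  gp <- generate_genotypes(base)
  wm <- generate_weight_model(base)
  risk <- drop(gp$genotypes$dosages[, wm$variant] %*% wm$weight)
  ph0 <- generate_phenotypes(gp$genotypes, wm, base, gp$pedigree)
  ph1 <- generate_phenotypes(gp$genotypes, wm, conf, gp$pedigree)
  expect_lt(abs(cor(ph0$education, risk)), 0.06)
  expect_gt(cor(ph1$education, risk), 0.15)
  # identical labels and other covariates when the switch is off twice
  expect_identical(ph0, generate_phenotypes(gp$genotypes, wm, base, gp$pedigree))
})
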