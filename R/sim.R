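#' Simulation configuration for synthetic cohorts
#'
#' Bundles every parameter needed to generate a synthetic cohort with known
#' ground truth: genotypes for sibship (multiplex) or unrelated (simplex)
#' designs, a sparse cis SNP-expression weight model, GWAS summary statistics
#' consistent with planted gene effects, and an onset phenotype drawn from a
#' logistic model with a family random intercept.
#'
#' Each gene owns a disjoint block of `snps_per_gene` cis variants (a
#' simplifying assumption that keeps induced marginal GWAS effects exact under
#' linkage equilibrium). The seed fully determines all outputs.
#'
#' @param n_families number of families (for a simplex design this is the
#'   number of unrelated individuals).
#' @param sibs_per_family affected siblings per family; 1 gives a simplex
#'   cohort of founders.
#' @param n_variants total number of biallelic variants.
#' @param n_genes number of genes with cis weight models.
#' @param snps_per_gene cis variants per gene; `n_genes * snps_per_gene` must
#'   not exceed `n_variants`.
#' @param maf_range range of ALT-allele frequencies, within (0, 0.5].
#' @param module_assignment named character vector mapping gene id to module
#'   id; by default every gene belongs to module `"M10"`.
#' @param true_gene_effects named numeric vector of log-odds of early onset
#'   per SD of a gene's true genetic expression; default all zero (global
#'   null).
#' @param gwas_gene_effects named numeric vector of gene effects on the GWAS
#'   trait (per SD of true expression) used to induce marginal variant
#'   effects in the summary statistics; defaults to `true_gene_effects`.
#' @param covariate_effects log-odds for the sex (male = 1) and per-year
#'   education covariates in the onset model.
#' @param confounding strength of genotype-covariate confounding: education
#'   gains `confounding` years per SD of the individual's genetic score
#'   (0, the default, keeps covariates independent of genotype; used for
#'   robustness studies).
#' @param gwas_n GWAS sample size controlling summary-statistic standard
#'   errors.
#' @param early_fraction target marginal fraction of early-onset cases; the
#'   intercept of the onset model is solved to match it. The default mirrors
#'   a 223/595 early/total split.
#' @param tau2 variance of the family-level random intercept in the onset
#'   model.
#' @param weight_sd standard deviation of the normal distribution the cis
#'   weights are drawn from.
#' @param ld_rho AR(1) correlation of the latent haplotype process; 0 gives
#'   linkage equilibrium, positive values give decaying LD blocks for use as
#'   a summary-TWAS LD reference.
#' @param seed integer seed; fully determines all generated objects.
#' @param geno_seed seed used by the genotype and phenotype draws only
#'   (defaults to `seed`). Two cohort configs sharing `seed` but differing
#'   in `geno_seed` share one genetic architecture (variants, weights,
#'   summary statistics) while drawing independent individuals, as in a
#'   multiplex + simplex two-sample design.
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_families = 300L,
                       sibs_per_family = 2L,
                       n_variants = 120L,
                       n_genes = 30L,
                       snps_per_gene = 4L,
                       maf_range = c(0.05, 0.5),
                       module_assignment = NULL,
                       true_gene_effects = NULL,
                       gwas_gene_effects = NULL,
                       covariate_effects = c(sex = 0, education = -0.2),
                       confounding = 0,
                       gwas_n = 320403L,
                       early_fraction = 223 / 595,
                       tau2 = 0.5,
                       weight_sd = 0.2,
                       ld_rho = 0,
                       seed = 1L,
                       geno_seed = NULL) {
  stopifnot(length(maf_range) == 2L, length(seed) == 1L)
  if (any(c(n_families, sibs_per_family, n_variants, n_genes) <= 0))
    stop("counts (n_families, sibs_per_family, n_variants, n_genes) must be positive")
  if (snps_per_gene < 0) stop("snps_per_gene must be non-negative")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (gwas_n <= 0) stop("gwas_n must be positive")
  if (tau2 < 0) stop("tau2 must be non-negative")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")

  genes <- sprintf("g%03d", seq_len(n_genes))
  if (is.null(module_assignment)) {
    module_assignment <- stats::setNames(rep("M10", n_genes), genes)
  }
  if (is.null(true_gene_effects)) {
    true_gene_effects <- stats::setNames(numeric(n_genes), genes)
  }
  if (is.null(gwas_gene_effects)) gwas_gene_effects <- true_gene_effects

  cfg <- list(
    n_families = as.integer(n_families),
    sibs_per_family = as.integer(sibs_per_family),
    n_variants = as.integer(n_variants),
    n_genes = as.integer(n_genes),
    snps_per_gene = as.integer(snps_per_gene),
    maf_range = as.numeric(maf_range),
    genes = genes,
    module_assignment = module_assignment,
    true_gene_effects = true_gene_effects,
    gwas_gene_effects = gwas_gene_effects,
    covariate_effects = covariate_effects,
    confounding = confounding,
    gwas_n = as.numeric(gwas_n),
    early_fraction = early_fraction,
    tau2 = tau2,
    weight_sd = weight_sd,
    ld_rho = ld_rho,
    seed = as.integer(seed),
    geno_seed = as.integer(if (is.null(geno_seed)) seed else geno_seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

# Variant metadata shared by the genotype, weight and summary-statistic
# generators so that ids, alleles and theoretical frequencies agree.
# Alleles are drawn from strand-unambiguous pairs so that harmonization does
# not silently drop simulated variants; ambiguous variants are constructed
# explicitly in tests.
.sim_variants <- function(config) {
  set.seed(config$seed + 1L)
  n <- config$n_variants
  pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), ncol = 2, byrow = TRUE)
  idx <- sample.int(nrow(pairs), n, replace = TRUE)
  data.frame(
    id = sprintf("v%05d", seq_len(n)),
    chrom = "1",
    pos = seq_len(n) * 10000L,
    ref = pairs[idx, 1L],
    alt = pairs[idx, 2L],
    maf = stats::runif(n, config$maf_range[1], config$maf_range[2]),
    info = 1.0,
    stringsAsFactors = FALSE
  )
}

# One haplotype panel: n x m matrix of 0/1 ALT alleles with allele
# frequencies `p` (length m). With rho > 0 alleles are thresholded from a
# latent AR(1) Gaussian so neighbouring variants are correlated.
.sim_haplotypes <- function(n, p, rho) {
  m <- length(p)
  if (rho == 0) {
    matrix(stats::rbinom(n * m, 1L, rep(p, each = n)), n, m)
  } else {
    z <- matrix(stats::rnorm(n * m), n, m)
    for (j in seq_len(m)[-1]) {
      z[, j] <- rho * z[, j - 1L] + sqrt(1 - rho^2) * z[, j]
    }
    (z < matrix(stats::qnorm(p), n, m, byrow = TRUE)) + 0L
  }
}

#' Generate genotype dosages for a sibship or simplex cohort
#'
#' Siblings within a family are drawn by Mendelian transmission from two
#' unobserved parents, so the expected within-sibship dosage correlation at a
#' variant is 0.5 (twice the sib-pair kinship). With `sibs_per_family = 1`
#' every individual is an unrelated founder. Parents are simulated but not
#' emitted, matching a patient-only design. Dosages are exact allele counts;
#' the INFO field is set to 1.0 (simulated genotypes are treated as observed).
#'
#' @param config a [sim_config()] object.
#' @return a list with `genotypes` (a [genotype_matrix()]) and `pedigree`
#'   (data frame with individual, family, role, founder).
#' @export
generate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  variants <- .sim_variants(config)
  set.seed(config$geno_seed + 2L)
  nf <- config$n_families
  ns <- config$sibs_per_family
  p <- variants$maf
  m <- length(p)

  # four parental haplotypes per family
  h <- lapply(1:4, function(i) .sim_haplotypes(nf, p, config$ld_rho))
  dosages <- matrix(0, nf * ns, m)
  for (s in seq_len(ns)) {
    pick1 <- matrix(stats::runif(nf * m) < 0.5, nf, m)
    pick2 <- matrix(stats::runif(nf * m) < 0.5, nf, m)
    hap1 <- ifelse(pick1, h[[1]], h[[2]])
    hap2 <- ifelse(pick2, h[[3]], h[[4]])
    dosages[(s - 1L) * nf + seq_len(nf), ] <- hap1 + hap2
  }

  fam <- rep(sprintf("F%04d", seq_len(nf)), times = ns)
  sib <- rep(seq_len(ns), each = nf)
  ids <- sprintf("%s_S%d", fam, sib)
  ord <- order(fam, sib)
  dosages <- dosages[ord, , drop = FALSE]
  pedigree <- data.frame(
    individual = ids[ord],
    family = fam[ord],
    role = "sib",
    founder = ns == 1L,
    stringsAsFactors = FALSE
  )
  rownames(dosages) <- pedigree$individual
  colnames(dosages) <- variants$id

  f <- colMeans(dosages) / 2
  variants$maf <- pmin(f, 1 - f)   # realized MAF
  geno <- genotype_matrix(dosages, variants)
  list(genotypes = geno, pedigree = pedigree)
}

#' Generate a sparse cis SNP-expression weight model
#'
#' Gene `j` owns the `j`-th disjoint block of `snps_per_gene` variants; its
#' weights are drawn from `N(0, weight_sd^2)`. The effect allele is the ALT
#' allele of the shared variant table. With `snps_per_gene = 0` every gene has
#' an empty weight set (downstream prediction must then exclude it).
#'
#' @param config a [sim_config()] object.
#' @return a `weight_model` data frame with columns gene, variant,
#'   ref_allele, eff_allele, weight, plus a `genes` attribute listing all
#'   genes and a zero `intercepts` attribute.
#' @export
generate_weight_model <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_genes * config$snps_per_gene > config$n_variants)
    stop("overlapping cis sets: n_genes * snps_per_gene exceeds n_variants")
  variants <- .sim_variants(config)
  set.seed(config$seed + 3L)
  spg <- config$snps_per_gene
  if (spg == 0L) {
    wm <- data.frame(gene = character(), variant = character(),
                     ref_allele = character(), eff_allele = character(),
                     weight = numeric(), stringsAsFactors = FALSE)
  } else {
    idx <- seq_len(config$n_genes * spg)
    wm <- data.frame(
      gene = rep(config$genes, each = spg),
      variant = variants$id[idx],
      ref_allele = variants$ref[idx],
      eff_allele = variants$alt[idx],
      weight = stats::rnorm(length(idx), 0, config$weight_sd),
      stringsAsFactors = FALSE
    )
  }
  weight_model(wm, genes = config$genes)
}

#' Construct a weight model object
#'
#' @param weights data frame with columns gene, variant, ref_allele,
#'   eff_allele, weight.
#' @param genes optional full gene list (including genes with empty weight
#'   sets); defaults to the genes present in `weights`.
#' @param intercepts optional named per-gene intercepts (used to track
#'   allele-flip constants); default zero.
#' @return the data frame with class `weight_model`.
#' @export
weight_model <- function(weights, genes = NULL, intercepts = NULL) {
  need <- c("gene", "variant", "ref_allele", "eff_allele", "weight")
  stopifnot(all(need %in% names(weights)))
  if (anyDuplicated(weights[, c("gene", "variant")]))
    stop("duplicate (gene, variant) pairs in weight model")
  if (any(!is.finite(weights$weight))) stop("weights must be finite")
  if (is.null(genes)) genes <- unique(weights$gene)
  if (is.null(intercepts)) intercepts <- stats::setNames(numeric(length(genes)), genes)
  structure(weights, genes = genes, intercepts = intercepts,
            class = c("weight_model", "data.frame"))
}

# SD of each gene's true genetic expression under linkage equilibrium:
# var(E_g) = sum_l w_l^2 * 2 p_l (1 - p_l), using theoretical frequencies.
.gene_expression_sd <- function(weights, variants) {
  p <- variants$maf[match(weights$variant, variants$id)]
  v2 <- weights$weight^2 * 2 * p * (1 - p)
  sds <- sqrt(tapply(v2, weights$gene, sum))
  sds[sds == 0] <- 1
  sds
}

#' Generate GWAS summary statistics consistent with planted gene effects
#'
#' The GWAS trait is modelled as a linear combination of standardized true
#' gene expressions with coefficients `gwas_gene_effects`. Under linkage
#' equilibrium (the generator's disjoint-cis design) the induced marginal
#' effect of variant `l` in gene `g` is `gamma_g * w_lg / sd(E_g)`. Observed
#' betas add noise with `SE = 1 / sqrt(2 f (1 - f) gwas_n)`; z and p are
#' consistent with beta/SE. Variants in no weight model have beta centred at
#' zero.
#'
#' @param config a [sim_config()] object.
#' @param weights the weight model generated from the same config.
#' @return a `sumstats` data frame (variant, eff_allele, other_allele, beta,
#'   se, z, p, freq, n).
#' @export
generate_summary_stats <- function(config, weights) {
  stopifnot(inherits(config, "sim_config"), inherits(weights, "weight_model"))
  variants <- .sim_variants(config)
  set.seed(config$geno_seed + 4L)  # noise is draw-level, like genotypes
  induced <- stats::setNames(numeric(config$n_variants), variants$id)
  if (nrow(weights) > 0) {
    sds <- .gene_expression_sd(weights, variants)
    gam <- config$gwas_gene_effects[weights$gene]
    gam[is.na(gam)] <- 0
    induced[weights$variant] <- gam * weights$weight / sds[weights$gene]
  }
  f <- variants$maf
  se <- 1 / sqrt(2 * f * (1 - f) * config$gwas_n)
  beta <- induced + stats::rnorm(config$n_variants, 0, se)
  z <- beta / se
  ss <- data.frame(
    variant = variants$id,
    eff_allele = variants$alt,
    other_allele = variants$ref,
    beta = beta, se = se, z = z,
    p = 2 * stats::pnorm(-abs(z)),
    freq = f,
    n = config$gwas_n,
    stringsAsFactors = FALSE
  )
  class(ss) <- c("sumstats", "data.frame")
  ss
}

#' Generate onset phenotypes and covariates from a logistic model
#'
#' Draws a binary early-onset label from
#' `logit P(early) = alpha + sum_g beta_g z(E_g) + covariates + u_f`,
#' where `E_g` is the true genetic expression (true weights applied to the
#' generated dosages), `beta_g` are `config$true_gene_effects`, `u_f` is a
#' family-level normal random intercept with variance `tau2`, and `alpha` is
#' solved so the expected early-onset fraction matches
#' `config$early_fraction`. Sex, education (years) and four synthetic
#' ancestry PC columns are emitted; by default they are generated
#' independently of genotype.
#'
#' A known per-individual score can be planted directly via `planted_score`
#' (it is z-standardized internally and enters with coefficient
#' `planted_log_or`), which makes the coefficient of the analyzed score the
#' exact estimand in parameter-recovery studies.
#'
#' @param genotypes a [genotype_matrix()].
#' @param weights the true weight model.
#' @param config a [sim_config()] object.
#' @param pedigree pedigree data frame from [generate_genotypes()].
#' @param planted_score optional numeric vector (one value per individual,
#'   in genotype row order) whose standardized form receives effect
#'   `planted_log_or`.
#' @param planted_log_or log-odds of early onset per SD of `planted_score`.
#' @return a phenotype data frame: individual, family, onset (1 = early),
#'   sex (1 = male), education, PC1..PC4.
#' @export
generate_phenotypes <- function(genotypes, weights, config, pedigree,
                                planted_score = NULL, planted_log_or = 0) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  X <- genotypes$dosages
  n <- nrow(X)
  set.seed(config$geno_seed + 5L)

  eta <- numeric(n)
  if (nrow(weights) > 0 && any(config$true_gene_effects != 0)) {
    for (g in names(config$true_gene_effects)) {
      b <- config$true_gene_effects[[g]]
      if (b == 0) next
      wg <- weights[weights$gene == g, ]
      if (nrow(wg) == 0) next
      e <- X[, wg$variant, drop = FALSE] %*% wg$weight
      if (stats::sd(e) > 0) eta <- eta + b * as.numeric(scale(e))
    }
  }
  if (!is.null(planted_score)) {
    stopifnot(length(planted_score) == n)
    if (stats::sd(planted_score) > 0)
      eta <- eta + planted_log_or * as.numeric(scale(planted_score))
  }

  sex <- stats::rbinom(n, 1L, 0.5)
  education <- stats::rnorm(n, 11, 2.5)
  if (config$confounding != 0 && stats::sd(eta) > 0)
    education <- education + config$confounding * as.numeric(scale(eta))
  education <- pmin(pmax(round(education), 6), 18)
  pcs <- matrix(stats::rnorm(n * 4), n, 4,
                dimnames = list(NULL, paste0("PC", 1:4)))
  eta <- eta + config$covariate_effects[["sex"]] * sex +
    config$covariate_effects[["education"]] * (education - mean(education))

  fam <- pedigree$family[match(rownames(X), pedigree$individual)]
  u <- stats::rnorm(length(unique(fam)), 0, sqrt(config$tau2))
  names(u) <- unique(fam)
  eta <- eta + u[fam]

  alpha <- stats::uniroot(
    function(a) mean(stats::plogis(a + eta)) - config$early_fraction,
    lower = -25, upper = 25
  )$root
  onset <- stats::rbinom(n, 1L, stats::plogis(alpha + eta))

  data.frame(
    individual = rownames(X),
    family = fam,
    onset = onset,
    sex = sex,
    education = education,
    pcs,
    stringsAsFactors = FALSE
  )
}

#' Generate a directed interaction network with planted hub genes
#'
#' Exactly `n_hubs` genes are planted as hubs regulating at least
#' `min_out_degree` distinct other genes; every remaining gene has
#' out-degree strictly below the threshold. Edge relation tags
#' (direct/indirect) are assigned at random.
#'
#' @param module_genes character vector of gene ids to wire.
#' @param n_hubs number of planted hub genes.
#' @param min_out_degree hub threshold (a hub regulates at least this many
#'   other genes); the default mirrors the "four or more" rule.
#' @param seed integer seed.
#' @return a [network_graph()] with a `planted_hubs` attribute.
#' @export
generate_network <- function(module_genes, n_hubs, min_out_degree = 4L, seed = 1L) {
  ng <- length(module_genes)
  if (n_hubs > ng) stop("n_hubs exceeds number of module genes")
  if (n_hubs > 0 && ng - 1L < min_out_degree)
    stop("infeasible degree demand: too few genes to reach min_out_degree")
  set.seed(seed)
  hubs <- if (n_hubs > 0) sort(sample(module_genes, n_hubs)) else character()
  from <- character(); to <- character()
  for (g in module_genes) {
    others <- setdiff(module_genes, g)
    d <- if (g %in% hubs) {
      min(min_out_degree + sample(0:2, 1L), length(others))
    } else {
      sample.int(min(min_out_degree, length(others) + 1L), 1L) - 1L  # 0 .. min-1
    }
    if (d > 0) {
      tg <- sample(others, d)
      from <- c(from, rep(g, d)); to <- c(to, tg)
    }
  }
  edges <- data.frame(
    from = from, to = to, directed = TRUE,
    relation = sample(c("direct", "indirect"), length(from), replace = TRUE),
    stringsAsFactors = FALSE
  )
  net <- network_graph(edges, focus = module_genes)
  attr(net, "planted_hubs") <- hubs
  net
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper running the genotype, weight-model, summary-statistic
#' and phenotype generators from one configuration.
#'
#' @inheritParams generate_phenotypes
#' @param config a [sim_config()] object.
#' @return list with genotypes, pedigree, weights, sumstats, phenotypes and
#'   the config itself.
#' @export
simulate_cohort <- function(config, planted_score = NULL, planted_log_or = 0) {
  gp <- generate_genotypes(config)
  wm <- generate_weight_model(config)
  ss <- generate_summary_stats(config, wm)
  ph <- generate_phenotypes(gp$genotypes, wm, config, gp$pedigree,
                            planted_score = planted_score,
                            planted_log_or = planted_log_or)
  list(genotypes = gp$genotypes, pedigree = gp$pedigree, weights = wm,
       sumstats = ss, phenotypes = ph, config = config)
}
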