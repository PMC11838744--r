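toy_expr <- function(values, genes, samples = NULL) {
  if (is.null(samples))
    samples <- sprintf("i%02d", seq_len(length(values) / length(genes)))
  m <- matrix(values, ncol = length(genes), dimnames = list(samples, genes))
  structure(m, class = c("expression_matrix", "matrix", "array"))
}

toy_twas <- function(genes, effect) {
  structure(
    data.frame(gene = genes, z = effect, effect = effect,
               p = 2 * pnorm(-abs(effect)), n_variants_used = 1,
               stringsAsFactors = FALSE),
    class = c("twas_result", "data.frame")
  )
}

test_that("gene scores are the elementwise product of effect and expression", {
  e <- toy_expr(c(1, 2, 3,   0.5, -1, 0,   2, 2, 2,   1, 0, -1),
                genes = c("gA", "gB", "gC", "gD"))
  tw <- toy_twas(c("gA", "gB", "gC", "gD"), c(2, 0, -1, 1))
  # gB has effect 0: constant raw score, flagged during standardization
  expect_warning(st <- gene_gers(e, tw), "zero-variance")
  # brute-force elementwise oracle
  for (g in colnames(e)) {
    eff <- tw$effect[tw$gene == g]
    expect_equal(st$raw[st$score == paste0("gene:", g)],
                 unname(eff * e[, g]), tolerance = 1e-12)
  }
  # effect 0 -> identically zero score; effect 1 -> score equals expression
  expect_true(all(st$raw[st$score == "gene:gB"] == 0))
  expect_equal(st$raw[st$score == "gene:gD"], unname(e[, "gD"]))
})

test_that("missing genes are skipped and zero overlap is an error", {
  e <- toy_expr(c(1, 2, 3), genes = "gA")
  tw <- toy_twas(c("gA", "gX"), c(1, 2))
  st <- gene_gers(e, tw)
  expect_equal(sort(unique(st$score)), "gene:gA")
  expect_true("gX" %in% attr(st, "skipped"))
  expect_error(gene_gers(e, toy_twas("gZ", 1)), "no overlap")
})

test_that("module scores sum gene scores; unions add; hubs partition", {
  set.seed(21)
  e <- toy_expr(rnorm(40), genes = paste0("g", 1:5))
  tw <- toy_twas(paste0("g", 1:5), c(1.5, -0.5, 2, 0.3, -1))
  gg <- gene_gers(e, tw)

  m1 <- module_definition("A", c("g1", "g2"))
  m2 <- module_definition("B", c("g3", "g5"))
  mu <- module_definition("U", c("g1", "g2", "g3", "g5"))
  s1 <- module_gers(gg, m1); s2 <- module_gers(gg, m2)
  su <- module_gers(gg, mu)
  expect_equal(s1$raw + s2$raw, su$raw, tolerance = 1e-12)

  # single-gene module equals that gene's score
  ss <- module_gers(gg, module_definition("S", "g4"))
  expect_equal(ss$raw, gg$raw[gg$score == "gene:g4"], tolerance = 1e-12)

  # hub subset + complement = module (raw scale)
  hub <- hub_gers(gg, c("g1", "g3"), id = "U")
  comp <- module_gers(gg, module_definition("C", c("g2", "g5")))
  expect_equal(hub$raw + comp$raw, su$raw, tolerance = 1e-12)
  expect_error(hub_gers(gg, character(0)), "empty")
  expect_error(module_gers(gg, module_definition("Z", "gZ")), "empty intersection")
})

test_that("module intersection respects a cross-cohort availability list", {
  e <- toy_expr(rnorm(24), genes = paste0("g", 1:3))
  tw <- toy_twas(paste0("g", 1:3), c(1, 1, 1))
  gg <- gene_gers(e, tw)
  m <- module_definition("M10", c("g1", "g2", "g3", "g9"))
  s <- module_gers(gg, m, available_genes = c("g1", "g3", "g7"))
  expect_setequal(attr(s, "genes_used"), c("g1", "g3"))
  expect_equal(s$raw,
               gg$raw[gg$score == "gene:g1"] + gg$raw[gg$score == "gene:g3"],
               tolerance = 1e-12)
})

test_that("PRS matches hand computation and brute-force dot products", {
  d <- matrix(c(0, 1, 2), ncol = 1, dimnames = list(c("a", "b", "c"), NULL))
  g <- toy_geno(d)
  ss <- data.frame(variant = "v001", eff_allele = "G", other_allele = "A",
                   beta = 0.2, se = 0.02, z = 10, p = 1e-5, freq = 0.3)
  st <- prs(g, ss, thresholds = 1.0)
  expect_equal(st$raw, c(0, 0.2, 0.4))

  set.seed(22)
  n <- 50; m <- 20
  d2 <- matrix(rbinom(n * m, 2, 0.3), n, m,
               dimnames = list(sprintf("i%02d", 1:n), NULL))
  g2 <- toy_geno(d2)
  betas <- rnorm(m, 0, 0.1)
  ps <- c(0.001, 0.004, 0.05, runif(m - 3))  # straddle both thresholds
  ss2 <- data.frame(variant = g2$variants$id, eff_allele = "G",
                    other_allele = "A", beta = betas, se = 0.05,
                    z = betas / 0.05, p = ps, freq = 0.3)
  st2 <- prs(g2, ss2, thresholds = c(0.01, 0.1))
  for (t in c(0.01, 0.1)) {
    keep <- ps < t
    oracle <- drop(d2 %*% ifelse(keep, betas, 0))
    expect_equal(st2$raw[st2$score == paste0("prs:", t)], unname(oracle),
                 tolerance = 1e-12)
  }
  # threshold nesting: variants used at t1 <= t2 are nested
  used <- attr(st2, "variants_used")
  expect_true(all(used[["0.01"]] %in% used[["0.1"]]))
})

test_that("PRS harmonizes alleles and flags empty thresholds", {
  d <- matrix(c(0, 1, 2, 2, 1, 0), ncol = 2,
              dimnames = list(c("a", "b", "c"), NULL))
  g <- toy_geno(d, ref = c("A", "C"), alt = c("G", "T"))
  ss <- data.frame(variant = c("v001", "v002"),
                   eff_allele = c("G", "C"), other_allele = c("A", "T"),
                   beta = c(0.2, 0.4), se = 0.02, z = 10, p = c(1e-5, 1e-6),
                   freq = 0.3)
  st <- prs(g, ss, thresholds = 1.0)
  # v002 effect allele is REF: dosage of C = 2 - ALT dosage
  oracle <- 0.2 * d[, 1] + 0.4 * (2 - d[, 2]) - 0.8  # constant absorbed by z
  expect_equal(scale(st$raw)[, 1], scale(oracle)[, 1], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_warning(st0 <- prs(g, ss, thresholds = 1e-10), "no variant")
  expect_true(all(st0$raw == 0) && all(st0$z == 0))
})

test_that("greedy clumping keeps the lowest-p variant of a correlated pair", {
  set.seed(23)
  x <- rbinom(300, 2, 0.4)
  d <- cbind(x, pmin(pmax(x + rbinom(300, 1, 0.05) - rbinom(300, 1, 0.05), 0), 2),
             rbinom(300, 2, 0.4))
  rownames(d) <- sprintf("i%03d", 1:300)
  g <- toy_geno(d)
  ss <- data.frame(variant = g$variants$id, eff_allele = "G",
                   other_allele = "A", beta = c(0.3, 0.2, 0.1), se = 0.05,
                   z = 6, p = c(1e-8, 1e-4, 1e-3), freq = 0.4)
  st <- prs(g, ss, thresholds = 1, clump = list(r2_max = 0.1, window = 5e5))
  used <- attr(st, "variants_used")[["1"]]
  expect_true("v001" %in% used)     # lowest p kept
  expect_false("v002" %in% used)    # near-duplicate removed
  expect_true("v003" %in% used)     # independent variant kept
})

test_that("standardization follows the sample-sd convention and is idempotent", {
  st <- structure(
    data.frame(sample = c("a", "b", "c"), score = "s", raw = c(1, 2, 3),
               z = NA_real_),
    class = c("score_table", "data.frame")
  )
  s1 <- standardize_scores(st)
  expect_equal(s1$z, c(-1, 0, 1))   # sample-sd (n-1) convention
  expect_equal(mean(s1$z), 0, tolerance = 1e-12)
  expect_equal(sd(s1$z), 1, tolerance = 1e-12)

  s1$raw <- s1$z
  s2 <- standardize_scores(s1)
  expect_equal(s2$z, s1$z, tolerance = 1e-12)

  cst <- st; cst$raw <- rep(5, 3)
  expect_warning(sc <- standardize_scores(cst), "zero-variance")
  expect_equal(sc$z, rep(0, 3))
  expect_equal(attr(sc, "flagged"), "s")
})
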