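#' Read GWAS summary statistics from TSV
#'
#' Tolerant of the usual column aliases: variant id (`variant`, `SNP`, `ID`,
#' `rsid`, `variant_id`), effect allele (`eff_allele`, `A1`, `EA`,
#' `effect_allele`), other allele (`other_allele`, `A2`, `OA`, `ref_allele`),
#' `beta` or `OR` (log-transformed), `se`, `z`, `p`, frequency (`freq`,
#' `FRQ`, `EAF`) and `n`. Missing z is rebuilt as beta/se; missing p from z
#' (two-sided normal); missing beta from z * se.
#'
#' @param path TSV file path.
#' @return a `sumstats` data frame.
#' @export
read_sumstats <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(tb) <- tolower(names(tb))
  pick <- function(aliases) {
    hit <- intersect(aliases, names(tb))
    if (length(hit) == 0) NULL else tb[[hit[1]]]
  }
  out <- data.frame(
    variant = pick(c("variant", "snp", "id", "rsid", "variant_id")),
    eff_allele = pick(c("eff_allele", "a1", "ea", "effect_allele")),
    other_allele = pick(c("other_allele", "a2", "oa", "ref_allele")),
    stringsAsFactors = FALSE
  )
  beta <- pick(c("beta", "b"))
  or <- pick(c("or"))
  if (is.null(beta) && !is.null(or)) beta <- log(or)
  se <- pick(c("se", "stderr"))
  z <- pick(c("z", "zscore", "stat"))
  p <- pick(c("p", "pval", "p_value"))
  if (is.null(z) && !is.null(beta) && !is.null(se)) z <- beta / se
  if (is.null(beta) && !is.null(z) && !is.null(se)) beta <- z * se
  if (is.null(p) && !is.null(z)) p <- 2 * stats::pnorm(-abs(z))
  if (is.null(z)) stop("cannot derive z-scores: need z, or beta/OR plus se")
  out$beta <- beta; out$se <- se; out$z <- z; out$p <- p
  out$freq <- pick(c("freq", "frq", "eaf", "maf"))
  out$n <- pick(c("n", "neff"))
  class(out) <- c("sumstats", "data.frame")
  out
}

# Align summary statistics to the effect alleles of a weight table.
# Returns z (and beta) on the weight's effect-allele scale; NA where the
# variant is absent or alleles cannot be reconciled.
.align_z <- function(weights, sumstats) {
  m <- match(weights$variant, sumstats$variant)
  z <- rep(NA_real_, nrow(weights))
  ok <- !is.na(m)
  same <- ok & sumstats$eff_allele[m] == weights$eff_allele &
    sumstats$other_allele[m] == weights$ref_allele
  swap <- ok & sumstats$eff_allele[m] == weights$ref_allele &
    sumstats$other_allele[m] == weights$eff_allele
  z[same] <- sumstats$z[m[same]]
  z[swap] <- -sumstats$z[m[swap]]
  z
}

#' Summary-statistics TWAS (gene-level z-scores)
#'
#' Combines GWAS variant z-scores with cis expression weights and an LD
#' reference panel into a gene-level association z-score:
#' \deqn{z_g = \sum_l w_{lg} (\sigma_l / \sigma_g) z_l,\qquad
#'       \sigma_g^2 = w^\top \Sigma w,}
#' where \eqn{\sigma_l} is the dosage SD of variant l in the reference panel
#' and \eqn{\Sigma} its dosage covariance (with a small ridge added to the
#' diagonal for numerical stability). Summary z-scores are aligned to the
#' weight effect alleles first (sign flip when swapped; irreconcilable
#' variants dropped and logged). Genes with no overlapping variants or with
#' \eqn{\sigma_g = 0} are excluded with a reason.
#'
#' @param weights a [weight_model()].
#' @param sumstats a `sumstats` data frame (see [read_sumstats()]).
#' @param ld_ref a [genotype_matrix()] covering the weight variants.
#' @param ridge diagonal shrinkage added to the reference covariance.
#' @param effect which statistic to report in the `effect` column (used
#'   downstream as the GeRS weight): the TWAS `"z"` itself (default) or the
#'   beta-like `"z_over_sigma"` = z / sigma_g.
#' @return a `twas_result` data frame (gene, z, effect, p,
#'   n_variants_used) with an `excluded` attribute naming excluded genes and
#'   reasons.
#' @export
summary_twas <- function(weights, sumstats, ld_ref, ridge = 1e-8,
                         effect = c("z", "z_over_sigma")) {
  stopifnot(inherits(weights, "weight_model"), inherits(ld_ref, "genotype_matrix"))
  effect <- match.arg(effect)
  # express all weights on the panel's ALT-dosage scale so that the panel
  # covariance applies; strand-ambiguity across datasets is the caller's
  # explicit harmonization step, not re-decided here
  weights <- harmonize_weights(weights, ld_ref, drop_ambiguous = FALSE)
  w <- as.data.frame(weights)
  w$z <- .align_z(weights, sumstats)
  genes <- unique(w$gene)
  rows <- vector("list", length(genes))
  excluded <- character()
  for (i in seq_along(genes)) {
    g <- genes[i]
    wg <- w[w$gene == g & !is.na(w$z) & w$variant %in% ld_ref$variants$id, ]
    if (nrow(wg) == 0) {
      excluded[g] <- "no_overlapping_variants"
      next
    }
    X <- ld_ref$dosages[, wg$variant, drop = FALSE]
    if (anyNA(X)) {
      mu <- colMeans(X, na.rm = TRUE)
      idx <- which(is.na(X), arr.ind = TRUE)
      X[idx] <- mu[idx[, 2]]
    }
    S <- stats::cov(X)
    diag(S) <- diag(S) + ridge
    sig_l <- sqrt(diag(S))
    sig_g <- sqrt(drop(t(wg$weight) %*% S %*% wg$weight))
    # sigma_g indistinguishable from the ridge floor means no genetic variance
    if (!is.finite(sig_g) || sig_g^2 <= 10 * ridge * sum(wg$weight^2)) {
      excluded[g] <- "zero_predicted_variance"
      next
    }
    zg <- sum(wg$weight * sig_l * wg$z) / sig_g
    rows[[i]] <- data.frame(
      gene = g, z = zg,
      effect = if (effect == "z") zg else zg / sig_g,
      p = 2 * stats::pnorm(-abs(zg)),
      n_variants_used = nrow(wg),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res)) stop("no gene could be scored against the LD reference")
  rownames(res) <- NULL
  structure(res, excluded = excluded, class = c("twas_result", "data.frame"))
}

#' Individual-level TWAS
#'
#' Per-gene regression of the phenotype on predicted expression plus
#' covariates; the reported z is the Wald statistic of the expression term.
#' The default binomial family matches a case/control phenotype; a gaussian
#' family is available for quantitative traits. Genes with (near-)constant
#' expression or separated fits are flagged and excluded from downstream
#' oracle comparisons rather than reported with unstable z.
#'
#' @param expression an `expression_matrix` from [predict_expression()].
#' @param phenotype binary (0/1) or numeric vector aligned to expression
#'   rows.
#' @param covariates optional data frame or matrix of covariates.
#' @param family a [stats::family] object (default `binomial()`).
#' @return a `twas_result` data frame with a logical `flagged` column.
#' @export
individual_twas <- function(expression, phenotype, covariates = NULL,
                            family = stats::binomial()) {
  stopifnot(nrow(expression) == length(phenotype))
  covdf <- if (is.null(covariates)) NULL else as.data.frame(covariates)
  genes <- colnames(expression)
  out <- data.frame(gene = genes, z = NA_real_, effect = NA_real_,
                    p = NA_real_, n_variants_used = NA_integer_,
                    flagged = FALSE, stringsAsFactors = FALSE)
  nv <- attr(expression, "n_variants")
  for (i in seq_along(genes)) {
    e <- expression[, i]
    if (stats::sd(e) == 0) {
      out$flagged[i] <- TRUE
      next
    }
    df <- data.frame(y = phenotype, e = e)
    if (!is.null(covdf)) df <- cbind(df, covdf)
    fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = family))
    co <- summary(fit)$coefficients
    if (!"e" %in% rownames(co) || !fit$converged || abs(co["e", 1]) > 15) {
      out$flagged[i] <- TRUE
      next
    }
    out$z[i] <- co["e", 1] / co["e", 2]
    out$effect[i] <- out$z[i]
    out$p[i] <- 2 * stats::pnorm(-abs(out$z[i]))
    if (!is.null(nv)) out$n_variants_used[i] <- nv[[genes[i]]]
  }
  structure(out, class = c("twas_result", "data.frame"))
}

#' Genes passing a significance threshold
#'
#' Strict inequality (`p < alpha`), sorted by p ascending. The default alpha
#' is the conventional genome-wide threshold 5e-8.
#'
#' @param twas a `twas_result`.
#' @param alpha significance threshold.
#' @return character vector of gene ids.
#' @export
significant_genes <- function(twas, alpha = 5e-8) {
  hit <- twas[!is.na(twas$p) & twas$p < alpha, ]
  hit$gene[order(hit$p)]
}

#' Per-variant association scan (synthetic GWAS)
#'
#' Tests each variant's ALT dosage against a binary phenotype and returns a
#' summary-statistics table in the same layout as [generate_summary_stats()].
#' The default `"score"` method uses the closed-form logistic score test
#' (fast, vectorized; beta is the one-step estimate U/V); `"wald"` fits a
#' per-variant logistic regression. Used to produce empirical summary
#' statistics from a simulated mega-cohort and to diagnose test-statistic
#' inflation (see [genomic_inflation()]).
#'
#' @param geno a [genotype_matrix()].
#' @param phenotype binary 0/1 vector aligned to genotype rows.
#' @param method `"score"` (default) or `"wald"`.
#' @return a `sumstats` data frame.
#' @export
gwas_scan <- function(geno, phenotype, method = c("score", "wald")) {
  method <- match.arg(method)
  stopifnot(inherits(geno, "genotype_matrix"),
            length(phenotype) == nrow(geno$dosages))
  X <- geno$dosages
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  y <- phenotype
  if (method == "score") {
    ybar <- mean(y)
    Xc <- scale(X, center = TRUE, scale = FALSE)
    U <- drop(crossprod(Xc, y - ybar))
    V <- ybar * (1 - ybar) * colSums(Xc^2)
    beta <- U / V
    se <- 1 / sqrt(V)
  } else {
    beta <- se <- numeric(ncol(X))
    for (j in seq_len(ncol(X))) {
      co <- summary(stats::glm(y ~ X[, j], family = stats::binomial()))$coefficients
      beta[j] <- co[2, 1]; se[j] <- co[2, 2]
    }
  }
  z <- beta / se
  f <- colMeans(X) / 2
  out <- data.frame(
    variant = geno$variants$id,
    eff_allele = geno$variants$alt,
    other_allele = geno$variants$ref,
    beta = beta, se = se, z = z,
    p = 2 * stats::pnorm(-abs(z)),
    freq = f, n = length(y),
    stringsAsFactors = FALSE
  )
  class(out) <- c("sumstats", "data.frame")
  out
}
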