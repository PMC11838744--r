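#' Harmonize a weight model against genotype alleles
#'
#' Aligns each weight variant to the ALT-dosage convention of the genotype
#' data. For a weight variant present in the genotypes:
#' \itemize{
#'   \item effect allele == ALT (other == REF): weight kept as is;
#'   \item effect allele == REF (other == ALT): weight negated and the
#'     per-gene intercept increased by `2 * weight` (dosage of the effect
#'     allele is `2 - ALT dosage`);
#'   \item alleles mismatch the genotype pair: variant dropped;
#'   \item strand-ambiguous pairs (A/T, C/G): dropped by default.
#' }
#' Variants absent from the genotype data are dropped. Nothing is fatal;
#' every drop is recorded in the `log` attribute with its reason.
#'
#' @param weights a [weight_model()].
#' @param geno a [genotype_matrix()].
#' @param drop_ambiguous drop strand-ambiguous variants (default TRUE).
#' @return harmonized `weight_model` (weights on the ALT-dosage scale,
#'   per-gene `intercepts` attribute tracking flip constants, `log`
#'   attribute with one row per dropped or flipped variant).
#' @export
harmonize_weights <- function(weights, geno, drop_ambiguous = TRUE) {
  stopifnot(inherits(weights, "weight_model"), inherits(geno, "genotype_matrix"))
  vtab <- geno$variants
  m <- match(weights$variant, vtab$id)
  ambiguous <- function(a, b) {
    (a == "A" & b == "T") | (a == "T" & b == "A") |
      (a == "C" & b == "G") | (a == "G" & b == "C")
  }
  action <- rep("keep", nrow(weights))
  action[is.na(m)] <- "drop_absent"
  ok <- !is.na(m)
  ref <- vtab$ref[m]; alt <- vtab$alt[m]
  amb <- ok & ambiguous(weights$eff_allele, weights$ref_allele)
  if (drop_ambiguous) action[amb] <- "drop_ambiguous"
  straight <- ok & weights$eff_allele == alt & weights$ref_allele == ref
  flipped <- ok & weights$eff_allele == ref & weights$ref_allele == alt
  action[ok & !straight & !flipped & action == "keep"] <- "drop_mismatch"
  action[flipped & action == "keep"] <- "flip"

  out <- weights
  fl <- action == "flip"
  intercepts <- attr(weights, "intercepts")
  if (any(fl)) {
    add <- tapply(2 * out$weight[fl], out$gene[fl], sum)
    intercepts[names(add)] <- intercepts[names(add)] + add
    out$weight[fl] <- -out$weight[fl]
    tmp <- out$eff_allele[fl]
    out$eff_allele[fl] <- out$ref_allele[fl]
    out$ref_allele[fl] <- tmp
  }
  keep <- action %in% c("keep", "flip")
  log <- data.frame(gene = weights$gene, variant = weights$variant,
                    action = action, stringsAsFactors = FALSE)
  res <- weight_model(as.data.frame(out)[keep, , drop = FALSE],
                      genes = attr(weights, "genes"),
                      intercepts = intercepts)
  attr(res, "log") <- log
  res
}

#' Predict genetically regulated expression
#'
#' Linear predictor over matched weight variants:
#' `E_hat[i, g] = intercept_g + sum_l w[l, g] * X[i, l]`. A missing dosage
#' contributes nothing for that individual (term omission, the common
#' practice) or is replaced by the variant mean when
#' `missing_action = "mean"`. Genes with zero matched variants are excluded
#' with a warning, never emitted as constant zero.
#'
#' @param geno a [genotype_matrix()].
#' @param weights a harmonized [weight_model()] (see [harmonize_weights()]).
#' @param missing_action `"omit"` (default) or `"mean"`.
#' @return an `expression_matrix`: individuals x genes matrix with
#'   attributes `n_variants` (weight variants used per gene),
#'   `dropped_genes` and `n_missing_terms`.
#' @export
predict_expression <- function(geno, weights, missing_action = c("omit", "mean")) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(weights, "weight_model"))
  missing_action <- match.arg(missing_action)
  w <- weights[weights$variant %in% geno$variants$id, , drop = FALSE]
  genes_all <- attr(weights, "genes")
  genes <- intersect(genes_all, unique(w$gene))
  dropped <- setdiff(genes_all, genes)
  if (length(dropped) > 0)
    warning(sprintf("%d gene(s) with no matched weight variants excluded: %s",
                    length(dropped), paste(utils::head(dropped, 5), collapse = ", ")))
  if (length(genes) == 0) stop("no gene has matched weight variants")

  X <- geno$dosages
  n_missing <- sum(is.na(X[, unique(w$variant), drop = FALSE]))
  if (anyNA(X)) {
    if (missing_action == "omit") {
      X[is.na(X)] <- 0
    } else {
      mu <- colMeans(X, na.rm = TRUE)
      idx <- which(is.na(X), arr.ind = TRUE)
      X[idx] <- mu[idx[, 2]]
    }
  }
  W <- matrix(0, ncol(geno$dosages), length(genes),
              dimnames = list(geno$variants$id, genes))
  W[cbind(w$variant, w$gene)] <- w$weight
  E <- X %*% W
  ic <- attr(weights, "intercepts")[genes]
  ic[is.na(ic)] <- 0
  E <- sweep(E, 2, ic, "+")
  rownames(E) <- rownames(geno$dosages)
  structure(E,
            n_variants = table(factor(w$gene, levels = genes)),
            dropped_genes = dropped,
            n_missing_terms = n_missing,
            class = c("expression_matrix", "matrix", "array"))
}
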