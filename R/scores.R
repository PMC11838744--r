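#' Define a coexpression module
#'
#' @param id module identifier.
#' @param genes character vector of member genes (must be unique).
#' @param note free-text provenance note.
#' @return an object of class `module_definition`.
#' @export
module_definition <- function(id, genes, note = "") {
  if (anyDuplicated(genes)) stop("genes must be unique within a module")
  structure(list(id = id, genes = genes, note = note),
            class = "module_definition")
}

#' Read module gene lists from a two-column file
#'
#' @param path TSV/whitespace file with columns module id, gene id (no
#'   header).
#' @return named list of [module_definition()] objects.
#' @export
read_modules <- function(path) {
  tb <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("module", "gene"))
  sp <- split(tb$gene, tb$module)
  mapply(function(id, g) module_definition(id, unique(g)),
         names(sp), sp, SIMPLIFY = FALSE)
}

# long-format score table constructor
.score_table <- function(sample, score, raw) {
  st <- data.frame(sample = sample, score = score, raw = raw,
                   z = NA_real_, stringsAsFactors = FALSE)
  class(st) <- c("score_table", "data.frame")
  st
}

#' Z-standardize a score table
#'
#' For each score, `z = (raw - mean) / sd` over the scored sample, with the
#' sample (n - 1) standard-deviation convention. Zero-variance scores are
#' flagged and their z set to 0.
#'
#' @param scores a `score_table` (long format: sample, score, raw, z).
#' @return the table with the z column filled; flagged score names in the
#'   `flagged` attribute.
#' @export
standardize_scores <- function(scores) {
  stopifnot(inherits(scores, "score_table"))
  flagged <- character()
  for (s in unique(scores$score)) {
    i <- scores$score == s
    x <- scores$raw[i]
    sdx <- stats::sd(x)
    if (is.na(sdx) || sdx == 0) {
      scores$z[i] <- 0
      flagged <- c(flagged, s)
    } else {
      scores$z[i] <- (x - mean(x)) / sdx
    }
  }
  if (length(flagged) > 0)
    warning("zero-variance score(s) flagged, z set to 0: ",
            paste(flagged, collapse = ", "))
  attr(scores, "flagged") <- flagged
  scores
}

#' Per-gene expression risk scores
#'
#' The gene-level risk score of individual i for gene g is the predicted
#' expression weighted by the gene's trait effect size from the TWAS:
#' `raw[i, g] = effect_g * E_hat[i, g]`. Genes absent from either input are
#' skipped (names recorded in the `skipped` attribute); zero overlap is an
#' error.
#'
#' @param expression an `expression_matrix` from [predict_expression()].
#' @param twas a `twas_result` supplying per-gene effect sizes.
#' @return a standardized `score_table` with score names `gene:<g>`.
#' @export
gene_gers <- function(expression, twas) {
  genes <- intersect(colnames(expression), twas$gene[!is.na(twas$effect)])
  if (length(genes) == 0) stop("no overlap between predicted genes and TWAS results")
  skipped <- union(setdiff(colnames(expression), genes),
                   setdiff(twas$gene, genes))
  eff <- twas$effect[match(genes, twas$gene)]
  raw <- sweep(expression[, genes, drop = FALSE], 2, eff, "*")
  st <- .score_table(
    sample = rep(rownames(expression), times = length(genes)),
    score = rep(paste0("gene:", genes), each = nrow(expression)),
    raw = as.vector(raw)
  )
  st <- standardize_scores(st)
  attr(st, "skipped") <- skipped
  st
}

# raw values of a set of gene scores as a samples x genes matrix
.gene_score_matrix <- function(gene_scores, genes) {
  wanted <- paste0("gene:", genes)
  sub <- gene_scores[gene_scores$score %in% wanted, ]
  samples <- unique(gene_scores$sample)
  m <- matrix(NA_real_, length(samples), length(genes),
              dimnames = list(samples, genes))
  m[cbind(sub$sample, sub("^gene:", "", sub$score))] <- sub$raw
  m
}

#' Module-aggregated expression risk score
#'
#' Sums the raw per-gene risk scores over the module's genes, after
#' intersecting the module list with the genes actually scored (and, when
#' given, with `available_genes`, e.g. the genes predicted in every cohort
#' of a multi-cohort analysis). The result is z-standardized.
#'
#' @param gene_scores a `score_table` from [gene_gers()].
#' @param module a [module_definition()].
#' @param available_genes optional gene universe to intersect with (such as
#'   genes predicted in both cohorts).
#' @param prefix score-name prefix, `"module"` by default.
#' @return a standardized `score_table` with one score
#'   `<prefix>:<module id>`; the genes actually summed are in the
#'   `genes_used` attribute.
#' @export
module_gers <- function(gene_scores, module, available_genes = NULL,
                        prefix = "module") {
  stopifnot(inherits(module, "module_definition"))
  scored <- sub("^gene:", "", grep("^gene:", unique(gene_scores$score), value = TRUE))
  genes <- intersect(module$genes, scored)
  if (!is.null(available_genes)) genes <- intersect(genes, available_genes)
  if (length(genes) == 0)
    stop("module ", module$id, ": empty intersection with scored genes")
  m <- .gene_score_matrix(gene_scores, genes)
  raw <- rowSums(m)
  st <- .score_table(sample = rownames(m),
                     score = paste0(prefix, ":", module$id),
                     raw = raw)
  st <- standardize_scores(st)
  attr(st, "genes_used") <- genes
  st
}

#' Hub-gene-aggregated expression risk score
#'
#' As [module_gers()] with the hub-gene list as the gene set: the raw score
#' is the sum of the hub genes' raw gene-level scores.
#'
#' @param gene_scores a `score_table` from [gene_gers()].
#' @param hub_genes nonempty character vector of hub gene ids.
#' @param id identifier used in the score name (`hub:<id>`).
#' @return a standardized `score_table`.
#' @export
hub_gers <- function(gene_scores, hub_genes, id = "M10") {
  if (length(hub_genes) == 0) stop("empty hub gene list")
  module_gers(gene_scores, module_definition(id, hub_genes), prefix = "hub")
}

#' P-value-thresholded polygenic risk scores
#'
#' For each threshold t, `PRS_i(t) = sum over variants with p < t of
#' beta_l * dosage_il`, with betas harmonized to the ALT-dosage convention
#' (sign flip when the summary effect allele is REF; mismatching or
#' strand-ambiguous variants dropped). Optional greedy LD clumping keeps the
#' lowest-p variant and removes neighbours with squared dosage correlation
#' above `r2_max` within `window` bases before scoring. Each threshold's
#' score is z-standardized; a threshold passed by no variant yields a
#' flagged all-zero score.
#'
#' @param geno a [genotype_matrix()].
#' @param sumstats a `sumstats` data frame.
#' @param thresholds p-value thresholds; the default six-value grid
#'   {5e-8, 1e-4, 1e-3, 0.01, 0.05, 0.1} pairs with a 0.05/6 Bonferroni
#'   significance cutoff.
#' @param clump `NULL` (off, appropriate for linkage-equilibrium data) or a
#'   list with `r2_max` (default 0.1) and `window` (default 5e5).
#' @param drop_ambiguous drop strand-ambiguous variants (default TRUE).
#' @return a standardized `score_table` with score names `prs:<threshold>`;
#'   the variants used per threshold are in the `variants_used` attribute.
#' @export
prs <- function(geno, sumstats, thresholds = c(5e-8, 1e-4, 1e-3, 0.01, 0.05, 0.1),
                clump = NULL, drop_ambiguous = TRUE) {
  stopifnot(inherits(geno, "genotype_matrix"))
  vt <- geno$variants
  m <- match(vt$id, sumstats$variant)
  ok <- !is.na(m)
  beta <- rep(NA_real_, nrow(vt))
  same <- ok & sumstats$eff_allele[m] == vt$alt & sumstats$other_allele[m] == vt$ref
  swap <- ok & sumstats$eff_allele[m] == vt$ref & sumstats$other_allele[m] == vt$alt
  beta[same] <- sumstats$beta[m[same]]
  beta[swap] <- -sumstats$beta[m[swap]]
  if (drop_ambiguous) {
    amb <- (vt$ref == "A" & vt$alt == "T") | (vt$ref == "T" & vt$alt == "A") |
      (vt$ref == "C" & vt$alt == "G") | (vt$ref == "G" & vt$alt == "C")
    beta[amb] <- NA_real_
  }
  p <- sumstats$p[m]
  usable <- which(!is.na(beta) & !is.na(p))

  if (!is.null(clump) && length(usable) > 1) {
    r2_max <- if (is.null(clump$r2_max)) 0.1 else clump$r2_max
    window <- if (is.null(clump$window)) 5e5 else clump$window
    ord <- usable[order(p[usable])]
    kept <- integer()
    for (i in ord) {
      near <- kept[vt$chrom[kept] == vt$chrom[i] &
                     abs(vt$pos[kept] - vt$pos[i]) <= window]
      if (length(near) > 0) {
        r2 <- suppressWarnings(
          stats::cor(geno$dosages[, i], geno$dosages[, near, drop = FALSE],
                     use = "pairwise.complete.obs"))^2
        if (any(r2 > r2_max, na.rm = TRUE)) next
      }
      kept <- c(kept, i)
    }
    usable <- sort(kept)
  }

  X <- geno$dosages
  if (anyNA(X)) X[is.na(X)] <- 0  # missing dosage contributes nothing
  pieces <- vector("list", length(thresholds))
  used <- list()
  for (k in seq_along(thresholds)) {
    t <- thresholds[k]
    idx <- usable[p[usable] < t]
    raw <- if (length(idx) == 0) {
      warning(sprintf("no variant passes threshold %g; raw and z set to 0", t))
      numeric(nrow(X))
    } else {
      drop(X[, idx, drop = FALSE] %*% beta[idx])
    }
    used[[as.character(t)]] <- vt$id[idx]
    pieces[[k]] <- .score_table(sample = rownames(X),
                                score = paste0("prs:", format(t)),
                                raw = raw)
  }
  st <- do.call(rbind, pieces)
  class(st) <- c("score_table", "data.frame")
  st <- suppressWarnings(standardize_scores(st))
  attr(st, "variants_used") <- used
  st
}

#' Reshape a score table to wide format
#'
#' One row per sample, one column per score carrying the z values (or raw
#' values), for merging with a phenotype table before model fitting.
#'
#' @param scores a `score_table` or a list of them (rbind-ed together).
#' @param value `"z"` (default) or `"raw"`.
#' @return data frame with column `individual` plus one column per score.
#' @export
scores_wide <- function(scores, value = c("z", "raw")) {
  value <- match.arg(value)
  if (is.list(scores) && !is.data.frame(scores)) {
    scores <- do.call(rbind, lapply(scores, as.data.frame))
  }
  wide <- stats::reshape(
    as.data.frame(scores)[, c("sample", "score", value)],
    idvar = "sample", timevar = "score", direction = "wide"
  )
  names(wide) <- sub(paste0("^", value, "\\."), "", names(wide))
  names(wide)[1] <- "individual"
  rownames(wide) <- NULL
  wide
}
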