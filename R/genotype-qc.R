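#' Construct a genotype matrix
#'
#' Container for an individuals-by-variants ALT-dosage matrix plus variant
#' metadata. Dosages must lie in [0, 2] (NA = missing); variant ids must be
#' unique. Variant identity is keyed on (chrom, pos, ref, alt) with `id` as
#' alias; coordinates are 1-based (VCF convention).
#'
#' @param dosages numeric matrix, individuals x variants, dimnames set to
#'   sample and variant ids.
#' @param variants data frame with columns id, chrom, pos, ref, alt and
#'   optionally maf, info. MAF is (re)computed as `min(f, 1 - f)` of the ALT
#'   dosage mean / 2 when absent; INFO defaults to 1.
#' @return an object of class `genotype_matrix` with elements `dosages`,
#'   `variants`, `samples`.
#' @export
genotype_matrix <- function(dosages, variants) {
  stopifnot(is.matrix(dosages), nrow(variants) == ncol(dosages))
  need <- c("id", "chrom", "pos", "ref", "alt")
  stopifnot(all(need %in% names(variants)))
  if (anyDuplicated(variants$id)) stop("variant ids must be unique")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  if (is.null(variants$maf)) {
    f <- colMeans(dosages, na.rm = TRUE) / 2
    variants$maf <- pmin(f, 1 - f)
  }
  if (is.null(variants$info)) variants$info <- 1.0
  colnames(dosages) <- variants$id
  structure(
    list(dosages = dosages, variants = variants,
         samples = rownames(dosages)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Read genotype dosages from VCF or dosage TSV
#'
#' For VCF the DS FORMAT field is preferred; when absent, dosage falls back
#' to the GT allele count. Missing genotypes are recorded as NA, never zero.
#' Per-variant INFO (imputation quality) is read from the `INFO=` key of the
#' VCF INFO column when present, else set to 1.
#'
#' @param path file path.
#' @param format `"vcf"` or `"dosage_tsv"` (the layout written by
#'   [write_dosage_tsv()]: variant metadata columns then one column per
#'   sample).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
    fmt_keys <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":")))
    if ("DS" %in% fmt_keys) {
      ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    } else if ("GT" %in% fmt_keys) {
      gt <- vcfR::extract.gt(vcf, element = "GT")
      ds <- apply(gt, 2, function(col) {
        sapply(strsplit(col, "[/|]"), function(a) {
          if (length(a) == 0 || any(a == ".") || any(is.na(a))) NA_real_
          else sum(a != "0")
        })
      })
      if (is.null(dim(ds))) ds <- matrix(ds, nrow = nrow(vcf@gt))
    } else {
      stop("format error: VCF has neither DS nor GT in FORMAT")
    }
    info <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "INFO")))
    info[is.na(info)] <- 1.0
    ids <- fix$ID
    ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
    variants <- data.frame(
      id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT, info = info, stringsAsFactors = FALSE
    )
    dosages <- t(ds)
    rownames(dosages) <- colnames(vcf@gt)[-1]
    genotype_matrix(dosages, variants)
  } else {
    tb <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    meta_cols <- c("id", "chrom", "pos", "ref", "alt", "info")
    if (!all(c("id", "chrom", "pos", "ref", "alt") %in% names(tb)))
      stop("parse error: dosage TSV must carry id, chrom, pos, ref, alt columns")
    samp <- setdiff(names(tb), meta_cols)
    dosages <- t(as.matrix(tb[, samp, drop = FALSE]))
    colnames(dosages) <- tb$id
    variants <- tb[, intersect(meta_cols, names(tb)), drop = FALSE]
    genotype_matrix(dosages, variants)
  }
}

#' Apply post-imputation variant filters
#'
#' Retains variants with imputation quality `INFO >= info_min` and minor
#' allele frequency `MAF >= maf_min` (removal rules INFO < threshold and
#' MAF < threshold; the boundary is kept). MAF is recomputed from the
#' dosage matrix before filtering. A variant failing both filters is
#' counted once, under the INFO reason.
#'
#' The default `maf_min = 0.01` is the conventional post-imputation cutoff;
#' the more aggressive 0.1 used in some family studies is available by
#' setting `maf_min = 0.1`.
#'
#' @param geno a [genotype_matrix()].
#' @param info_min minimum INFO score (default 0.8).
#' @param maf_min minimum minor allele frequency.
#' @param p_values optional association p-values for the same sample; when
#'   given, the genomic inflation factor is computed and recorded in the
#'   report.
#' @return list with `genotypes` (filtered) and `report` (class
#'   `qc_report`: variants_in, removed_info, removed_maf, variants_out,
#'   lambda_gc).
#' @export
apply_qc <- function(geno, info_min = 0.8, maf_min = 0.01, p_values = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (info_min < 0 || info_min > 1 || maf_min < 0 || maf_min > 1)
    stop("thresholds must lie in [0, 1]")
  f <- colMeans(geno$dosages, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  geno$variants$maf <- maf
  fail_info <- geno$variants$info < info_min
  fail_maf <- maf < maf_min & !fail_info
  keep <- !fail_info & !fail_maf
  report <- structure(
    list(
      variants_in = ncol(geno$dosages),
      removed_info = sum(fail_info),
      removed_maf = sum(fail_maf),
      variants_out = sum(keep),
      lambda_gc = if (is.null(p_values)) NA_real_ else genomic_inflation(p = p_values)
    ),
    class = "qc_report"
  )
  out <- genotype_matrix(geno$dosages[, keep, drop = FALSE],
                         geno$variants[keep, , drop = FALSE])
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "QC: %d variants in, %d removed (INFO), %d removed (MAF), %d out; lambda_gc = %s\n",
    x$variants_in, x$removed_info, x$removed_maf, x$variants_out,
    ifelse(is.na(x$lambda_gc), "NA", format(x$lambda_gc, digits = 4))
  ))
  invisible(x)
}

#' Ancestry principal components from dosages
#'
#' Top-k principal components of the column-standardized dosage matrix
#' (missing dosages mean-imputed per variant, zero-variance variants
#' dropped). Sign convention: within each component the largest-magnitude
#' variant loading is made positive, so output is reproducible.
#'
#' @param geno a [genotype_matrix()].
#' @param k number of components (default 4).
#' @return an n x k matrix of PC scores (columns PC1..PCk) with attributes
#'   `loadings` and `var_explained`.
#' @export
compute_pcs <- function(geno, k = 4L) {
  stopifnot(inherits(geno, "genotype_matrix"))
  X <- geno$dosages
  if (nrow(X) < k + 1L) stop("need at least k + 1 samples")
  # mean-impute missing dosages (PCA only)
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  sds <- apply(X, 2, stats::sd)
  X <- X[, sds > 0, drop = FALSE]
  Xs <- scale(X)
  sv <- svd(Xs)
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  if (k > rank) stop("k exceeds the rank of the dosage matrix")
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(rownames(geno$dosages), paste0("PC", seq_len(k)))
  attr(scores, "loadings") <- loadings
  attr(scores, "var_explained") <- sv$d[seq_len(k)]^2 / sum(sv$d^2)
  scores
}

#' Genomic inflation factor (lambda)
#'
#' `lambda = median(chi^2_1 statistics) / 0.4549364` (the median of the
#' 1-df chi-squared distribution). P-values are converted through the
#' inverse chi-squared survival function.
#'
#' @param p vector of p-values in (0, 1]; ignored when `chi2` is given.
#' @param chi2 vector of 1-df chi-squared statistics.
#' @return the inflation factor (1 under a calibrated null).
#' @export
genomic_inflation <- function(p = NULL, chi2 = NULL) {
  if (is.null(chi2)) {
    if (is.null(p) || length(p) == 0) stop("supply p or chi2")
    if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
    chi2 <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  }
  if (length(chi2) == 0) stop("empty input")
  stats::median(chi2) / stats::qchisq(0.5, df = 1)
}
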