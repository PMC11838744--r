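#' Write a genotype matrix as VCF 4.2 with a DS FORMAT field
#'
#' Plain-text VCF with per-variant `INFO=` (imputation quality) in the INFO
#' column and per-sample ALT dosages in the DS FORMAT field (missing
#' dosages written as `.`). Round-trips through [read_genotypes()].
#'
#' @param geno a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  v <- geno$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation quality\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"ALT allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$samples), collapse = "\t")
  ), con)
  ds <- format(round(t(geno$dosages), 6), trim = TRUE, scientific = FALSE)
  ds[is.na(t(geno$dosages))] <- "."
  lines <- paste(
    v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS",
    paste0("INFO=", format(v$info, trim = TRUE)), "DS",
    apply(ds, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(lines, con)
  invisible(path)
}

#' Write a genotype matrix as a dosage TSV
#'
#' Columns: id, chrom, pos, ref, alt, info, then one column per sample.
#'
#' @inheritParams write_vcf
#' @export
write_dosage_tsv <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  tb <- cbind(geno$variants[, c("id", "chrom", "pos", "ref", "alt", "info")],
              as.data.frame(t(geno$dosages)))
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a weight model as TSV (PredictDB-style columns)
#'
#' Columns: gene, rsid, varID, ref_allele, eff_allele, weight.
#'
#' @param weights a [weight_model()].
#' @param path output path.
#' @export
write_weights <- function(weights, path) {
  tb <- data.frame(gene = weights$gene, rsid = weights$variant,
                   varID = weights$variant, ref_allele = weights$ref_allele,
                   eff_allele = weights$eff_allele, weight = weights$weight)
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a weight model from TSV
#'
#' Accepts the layout of [write_weights()] (gene, rsid/varID, ref_allele,
#' eff_allele, weight) or the plain columns gene, variant, ref_allele,
#' eff_allele, weight.
#'
#' @param path TSV path.
#' @return a [weight_model()].
#' @export
read_weights <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!"variant" %in% names(tb)) {
    vcol <- intersect(c("rsid", "varID"), names(tb))[1]
    tb$variant <- tb[[vcol]]
  }
  weight_model(tb[, c("gene", "variant", "ref_allele", "eff_allele", "weight")])
}

#' Write summary statistics, phenotypes, pedigree or edges as TSV
#'
#' Thin `write.table` wrappers with the standard column layouts.
#'
#' @param x the object (data frame).
#' @param path output path.
#' @name write_tsv_helpers
NULL

#' @rdname write_tsv_helpers
#' @export
write_sumstats <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_helpers
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a QC report as JSON
#'
#' @param report a `qc_report` from [apply_qc()].
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  fields <- c("variants_in", "removed_info", "removed_maf", "variants_out")
  vals <- vapply(fields, function(f) sprintf("\"%s\": %d", f, report[[f]]),
                 character(1))
  lam <- if (is.na(report$lambda_gc)) "null" else
    format(report$lambda_gc, digits = 10)
  writeLines(paste0("{", paste(c(vals, sprintf("\"lambda_gc\": %s", lam)),
                               collapse = ", "), "}"), path)
  invisible(path)
}

#' Read a gene-interaction edge list from TSV
#'
#' Columns: from, to, and optionally directed (logical) and relation.
#'
#' @param path TSV path.
#' @return edge data frame suitable for [build_networks()].
#' @export
read_edges <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
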