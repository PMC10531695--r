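#' Read a genotype matrix from VCF or TSV
#'
#' VCF records are parsed with vcfR; only biallelic sites are kept
#' (multi-allelic records are dropped and counted) and GT fields are
#' mapped to alternate-allele dosages 0/1/2 with `.` as missing. The TSV
#' dialect is genotypes as rows, markers as columns, header row of marker
#' ids, `NA` for missing.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return Dosage matrix (genotypes x markers); attribute
#'   `n_multiallelic_dropped` counts rejected VCF records.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  assert_that(file.exists(path), paste("no such file:", path))
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0) abort("VCF contains zero markers")
  biallelic <- vcfR::is.biallelic(vcf)
  n_dropped <- sum(!biallelic)
  if (n_dropped > 0) vcf <- vcf[biallelic, ]
  if (nrow(vcf@fix) == 0) abort("no biallelic markers in VCF")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean %in% c("0/0")] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean %in% c("1/1")] <- 2L
  bad <- !is.na(clean) & !(clean %in% c("0/0", "0/1", "1/0", "1/1",
                                        "./.", ".", "./0", "0/."))
  if (any(bad)) {
    first <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf("malformed GT at marker %s, sample %s",
                  rownames(gt)[first[1]], colnames(gt)[first[2]]))
  }
  ids <- vcf@fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(vcf@fix[, "CHROM"], ":", vcf@fix[, "POS"])[is.na(ids) | ids == "."]
  rownames(dos) <- ids
  out <- t(dos) # genotypes as rows
  attr(out, "n_multiallelic_dropped") <- n_dropped
  out
}

read_genotypes_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                   check.names = FALSE)
  if (ncol(df) == 0) abort("genotype TSV contains zero markers")
  out <- as.matrix(df)
  storage.mode(out) <- "double"
  bad <- !is.na(out) & !(out %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf("malformed dosage at row %d (genotype %s), marker %s",
                  idx[1] + 1L, rownames(out)[idx[1]], colnames(out)[idx[2]]))
  }
  out
}

#' Write a genotype matrix as TSV
#' @param G Dosage matrix.
#' @param path Output path.
#' @export
write_genotype_tsv <- function(G, path) {
  df <- as.data.frame(G)
  write.table(df, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Write a genotype matrix as a minimal biallelic VCF
#'
#' Emits VCFv4.2 text with GT-only FORMAT; integer dosages map to 0/0,
#' 0/1, 1/1 and missing to ./.. Chromosome and position come from the
#' matrix's `marker_meta` attribute when present.
#'
#' @param G Integer dosage matrix (mean-imputed matrices cannot be
#'   written; round or write TSV instead).
#' @param path Output path.
#' @export
write_genotype_vcf <- function(G, path) {
  vals <- G[!is.na(G)]
  assert_that(all(vals %in% c(0, 1, 2)),
              "VCF output needs integer dosages in {0, 1, 2}")
  meta <- attr(G, "marker_meta")
  m <- ncol(G)
  chrom <- if (!is.null(meta)) meta$chrom else rep(1L, m)
  pos <- if (!is.null(meta)) meta$pos else seq_len(m)
  gt_map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G)), collapse = "\t")
  )
  body <- vapply(seq_len(m), function(j) {
    gts <- ifelse(is.na(G[, j]), "./.", gt_map[as.character(G[, j])])
    paste(c(chrom[j], pos[j], colnames(G)[j], "A", "T", ".", "PASS", ".",
            "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a phenotype table
#'
#' Validates the CSV layout (genotype_id, n_level, GY, Ns, with optional
#' Nt and NUE), restricts `n_level` to LN/HN, rejects rows with
#' non-positive nitrogen supplied (counted in the
#' `n_rejected_nonpositive_ns` attribute) and fills NUE = GY / Ns where
#' absent.
#'
#' @param path CSV path.
#' @return Phenotype tibble.
#' @export
read_phenotypes <- function(path) {
  assert_that(file.exists(path), paste("no such file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("genotype_id", "n_level", "GY", "Ns")
  missing <- setdiff(required, names(df))
  if (length(missing))
    abort(paste("phenotype file lacks required column(s):",
                paste(missing, collapse = ", ")))
  bad_level <- setdiff(unique(df$n_level), c("LN", "HN"))
  if (length(bad_level))
    abort(paste("unknown n_level value(s):", paste(bad_level, collapse = ", ")))
  n_bad <- sum(!is.finite(df$Ns) | df$Ns <= 0)
  if (n_bad > 0) df <- df[is.finite(df$Ns) & df$Ns > 0, ]
  if (!"NUE" %in% names(df)) df$NUE <- NA_real_
  fill <- is.na(df$NUE)
  df$NUE[fill] <- df$GY[fill] / df$Ns[fill]
  out <- tibble::as_tibble(df)
  attr(out, "n_rejected_nonpositive_ns") <- n_bad
  out
}

#' Write a phenotype table as CSV
#' @param phenotypes Phenotype tibble.
#' @param path Output path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a kinship matrix as TSV with ids
#' @param K Kinship matrix.
#' @param path File path.
#' @export
write_kinship_tsv <- function(K, path) {
  write.table(as.data.frame(K), path, sep = "\t", quote = FALSE,
              col.names = NA)
  invisible(path)
}

#' @rdname write_kinship_tsv
#' @export
read_kinship_tsv <- function(path) {
  as.matrix(read.table(path, header = TRUE, sep = "\t", row.names = 1,
                       check.names = FALSE))
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
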